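# Independent oracles and fixture builders used across the suite.

# Proximal-gradient ascent (ISTA with backtracking) on the exact penalized
# log-likelihood: an algorithm family independent of the block coordinate
# descent under test.
istaGlasso <- function(R, lam, iters = 60000, tol = 1e-13) {
    p <- ncol(R)
    Th <- diag(p)
    eta <- 0.1
    obj <- function(Th) {
        d <- determinant(Th, logarithm = TRUE)
        if (d$sign <= 0) return(-Inf)
        off <- Th; diag(off) <- 0
        as.numeric(d$modulus) - sum(R * Th) - lam * sum(abs(off))
    }
    fo <- obj(Th)
    for (it in seq_len(iters)) {
        G <- solve(Th) - R
        repeat {
            Tn <- Th + eta * G
            off <- Tn - diag(diag(Tn))
            off <- sign(off) * pmax(abs(off) - eta * lam, 0)
            Tn <- off + diag(diag(Tn))
            fn <- obj(Tn)
            if (is.finite(fn) && fn >= fo - 1e-15) break
            eta <- eta / 2
            if (eta < 1e-12) break
        }
        if (!is.finite(fn)) break
        if (abs(fn - fo) < tol && it > 50) { Th <- Tn; break }
        Th <- Tn
        fo <- fn
        if (it %% 100 == 0) eta <- min(eta * 2, 0.5)
    }
    Th
}

# Pearson chi-square on a 2x2 prevalence table from first principles
# (expected counts under independence), no continuity correction.
pearsonChi2 <- function(n1, k1, n2, k2) {
    obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L)
    exp <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    sum((obs - exp)^2 / exp)
}

# Spearman correlation from first principles: midranks computed by hand,
# then the Pearson product-moment formula.
spearmanByHand <- function(x, y) {
    midrank <- function(v) {
        r <- numeric(length(v))
        for (i in seq_along(v))
            r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
        r
    }
    rx <- midrank(x); ry <- midrank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# scale a draw to its exact target (sample) variance: Monte-Carlo
# variance reduction so recovery tests isolate estimator error
scaleToVar <- function(x, v) {
    (x - mean(x)) / stats::sd(x) * sqrt(v)
}

# zero-inflated meal matrix drawn from a planted latent model
latentMealSample <- function(planted, n, prev, seed, mu = 1, sigma = 0.6) {
    set.seed(seed)
    p <- ncol(planted$Sigma)
    tau <- thresholdsFromPrevalence(rep(prev, p))
    Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(planted$Sigma)
    X <- exp(mu + sigma * Z) * sweep(Z, 2L, tau, ">")
    colnames(X) <- paste0("g", seq_len(p))
    X
}

# MealExperiment straight from a meals x groups matrix
mealsFromMatrix <- function(X, mealType = "lunch",
                            participant = NULL, trimester = 1L) {
    if (is.null(participant))
        participant <- paste0("P", seq_len(nrow(X)))
    cd <- S4Vectors::DataFrame(
        participant_id = participant,
        recall_id = paste0(participant, "_R", trimester),
        meal_type = rep_len(mealType, nrow(X)),
        occasion_index = seq_len(nrow(X)),
        trimester = rep_len(as.integer(trimester), nrow(X)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(grams = t(X)), colData = cd)
    new("MealExperiment", se)
}

# small well-formed recall record table
toyRecords <- function() {
    data.frame(
        participant_id = c("P1", "P1", "P2"),
        recall_id = c("P1_R1", "P1_R1", "P2_R1"),
        trimester = c(1L, 1L, 2L),
        occasion_index = c(1L, 1L, 1L),
        occasion_label = c("breakfast", "breakfast", "lunch"),
        food_code = c("FC01A", "FC02A", "FC01A"),
        amount_g = c(120, 30, 200),
        energy_kcal = c(72, 110, 120),
        stringsAsFactors = FALSE)
}

writeRecords <- function(df) {
    f <- tempfile(fileext = ".tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}

# hand-built two-community graph used by the cartography tests:
# community A = K4 on a,b,c,d (a also linked to community B),
# community B = star e-(f,g,h) plus ring f-g, g-h; i,j isolated pair
# appended as their own community
cartographyFixture <- function() {
    el <- rbind(
        c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d"),
        c("c", "d"),
        c("a", "e"),
        c("e", "f"), c("e", "g"), c("e", "h"), c("f", "g"), c("g", "h"),
        c("i", "j"))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::E(g)$weight <- 1
    memb <- c(a = 1L, b = 1L, c = 1L, d = 1L,
              e = 2L, f = 2L, g = 2L, h = 2L, i = 3L, j = 3L)
    list(graph = g, membership = memb)
}
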