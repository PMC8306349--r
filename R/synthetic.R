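#' Default food-group scheme used by the synthetic cohort
#'
#' Thirty-six named groups typical of a 40-group FNDDS-style scheme
#' (beverages, grains, vegetables, proteins, fats, sweets, mixed dishes)
#' plus four placeholder groups. Real analyses supply their own taxonomy;
#' this scheme only gives the generator realistic labels.
#'
#' @return character vector of 40 group names.
#' @export
defaultFoodGroups <- function() c(
    "water", "milk", "coffee_tea", "sugar_sweetened_beverages",
    "fruit_juice", "fruits", "other_vegetables", "red_orange_vegetables",
    "green_vegetables", "potatoes", "fried_potatoes", "white_bread",
    "whole_grain_bread", "quick_breads", "rte_cereals_high_sugar",
    "rte_cereals_low_sugar", "cooked_grains", "pasta_based_dishes",
    "sandwiches", "savory_pies", "soups", "cheese", "meat", "poultry",
    "fish", "eggs", "cured_meat", "protein_patties", "nuts", "solid_fats",
    "oils", "sauces", "mayonnaise_salads", "sweets", "cakes_cookies",
    "salty_snacks", "other_foods_1", "other_foods_2", "other_foods_3",
    "other_foods_4")

# hand-set energy densities (kcal/g), aligned with defaultFoodGroups()
.defaultEnergyDensity <- function(groups = defaultFoodGroups()) {
    dens <- c(0, 0.6, 0.05, 0.4, 0.45, 0.6, 0.3, 0.35, 0.25, 0.9, 3.0,
              2.6, 2.5, 3.3, 3.8, 3.7, 1.2, 1.5, 2.4, 2.6, 0.5, 3.5, 2.2,
              1.9, 1.6, 1.5, 3.0, 2.3, 6.0, 7.5, 8.8, 1.0, 3.0, 3.4, 4.0,
              5.0, 1.5, 1.5, 1.5, 1.5)
    setNames(dens[seq_along(groups)], groups)
}

# hand-set base portion grams per eating occasion, aligned with
# defaultFoodGroups(). These are the lognormal location, not the mean:
# the single-hurdle conditioning (amounts drawn only when the latent
# exceeds its threshold) inflates realized amounts by ~1.5-3.5x, so the
# base values sit below typical portions; the overall scale is calibrated
# so simulated recall totals centre near 2000 kcal/day with small
# implausible tails on both sides
.defaultPortionGrams <- function(groups = defaultFoodGroups()) {
    g <- 0.41 * c(300, 170, 220, 200, 140, 90, 60, 50, 45, 80, 55, 35,
                  35, 45, 28, 28, 80, 90, 100, 70, 180, 22, 55, 55, 45,
                  45, 22, 45, 16, 8, 8, 25, 45, 22, 38, 22, 25, 25, 25,
                  25)
    setNames(g[seq_along(groups)], groups)
}

#' Default synthetic-cohort configuration
#'
#' The defaults emulate the data structure of a pregnancy 24-h-recall
#' cohort: 120 participants per diet-quality stratum, up to three recalls
#' each (one per trimester; later recalls completed with probability
#' 0.85), breakfast/lunch/dinner plus 0-3 snack occasions per recall, 40
#' food groups with episodic consumption (per-group prevalence decaying
#' geometrically from 0.70 so roughly a third of groups fall under the 5\%
#' network filter), lognormal gram amounts, a participant-level latent
#' variance share \code{rho_b = 0.15}, and a planted sparse precision
#' matrix per meal type and stratum.
#'
#' @param nParticipants participants per stratum.
#' @param nGroups number of food groups.
#' @param rho_b participant share of latent variance, in [0,1).
#' @param sparsity expected fraction of off-diagonal precision entries
#'   that are nonzero in each planted model.
#' @param strength magnitude range of planted partial correlations.
#' @return a config list understood by \code{\link{simulateCohort}}.
#' @export
defaultGeneratorConfig <- function(nParticipants = 120L, nGroups = 40L,
                                   rho_b = 0.15, sparsity = 0.05,
                                   strength = c(0.35, 0.5)) {
    groups <- defaultFoodGroups()[seq_len(nGroups)]
    list(
        nParticipants = nParticipants,
        strata = c("low", "mid", "high"),
        mealTypes = c("breakfast", "lunch", "dinner", "snack"),
        recallProb = c(1, 0.85, 0.85),
        snackCountProb = c(`0` = 0.2, `1` = 0.4, `2` = 0.3, `3` = 0.1),
        groups = groups,
        prevalence = setNames(0.70 * 0.9^(seq_len(nGroups) - 1L), groups),
        rho_b = rho_b,
        sparsity = sparsity,
        strength = strength,
        maxDegree = 2L,
        logMean = setNames(log(.defaultPortionGrams(groups)), groups),
        logSd = setNames(rep(0.6, nGroups), groups),
        energyDensity = .defaultEnergyDensity(groups),
        supperProb = 0.15,
        drinkOccasionProb = 0.10,
        supplementOccasionProb = 0.10,
        heiMeans = c(low = 45, mid = 60, high = 75),
        heiSd = 6)
}

#' Generate a sparse planted precision matrix
#'
#' Builds a symmetric positive-definite precision matrix with roughly
#' \code{sparsity} of its off-diagonal entries nonzero. Support is sampled
#' with a per-node degree cap (default 2) so the diagonal inflation needed
#' for positive definiteness stays small and the planted partial
#' correlations keep their intended magnitude; the matrix is rescaled to
#' unit diagonal, so the planted partial correlation of edge (i,j) is
#' \eqn{-\Theta_{ij}}. Redraws (bounded) until every planted
#' \eqn{|partial correlation| \ge minPcor}.
#'
#' @param p number of variables (>= 2).
#' @param sparsity target fraction of nonzero off-diagonal entries (0,1).
#' @param strength range of edge magnitudes.
#' @param seed RNG seed; same seed gives an identical matrix.
#' @param maxDegree per-node cap on planted edges.
#' @param minPcor minimum planted absolute partial correlation.
#' @return list: \code{Theta} (precision, unit diagonal), \code{Sigma}
#'   (implied latent correlation, unit diagonal), \code{support} (logical
#'   matrix of planted edges), \code{pcor} (planted partial correlations).
#' @export
generateSparsePrecision <- function(p, sparsity, strength = c(0.35, 0.5),
                                    seed = 1L, maxDegree = 2L,
                                    minPcor = 0.25) {
    stopifnot(p >= 2L, sparsity >= 0, sparsity < 1)
    set.seed(seed)
    npairs <- p * (p - 1L) / 2L
    k <- round(sparsity * npairs)
    for (try in seq_len(50L)) {
        pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
        pairs <- pairs[sample.int(npairs), , drop = FALSE]
        deg <- integer(p)
        Theta <- diag(p)
        taken <- 0L
        for (r in seq_len(npairs)) {
            if (taken >= k) break
            i <- pairs[r, 1L]; j <- pairs[r, 2L]
            if (deg[i] >= maxDegree || deg[j] >= maxDegree) next
            v <- runif(1L, strength[1L], strength[2L]) *
                sample(c(-1, 1), 1L)
            Theta[i, j] <- Theta[j, i] <- v
            deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
            taken <- taken + 1L
        }
        ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
        margin <- 0.05
        if (ev < margin) diag(Theta) <- diag(Theta) + (margin - ev)
        d <- sqrt(diag(Theta))
        Theta <- Theta / tcrossprod(d)          # unit diagonal
        pcor <- -Theta; diag(pcor) <- 1
        support <- Theta != 0 & !diag(p)
        if (k == 0L || min(abs(pcor[support])) >= minPcor) {
            Sigma <- solve(Theta)
            Sigma <- Sigma / tcrossprod(sqrt(diag(Sigma)))
            return(list(Theta = Theta, Sigma = Sigma, support = support,
                        pcor = pcor))
        }
    }
    stop("could not plant a precision matrix with |pcor| >= ", minPcor,
         "; lower sparsity, strength, or minPcor")
}

#' Latent consumption thresholds from target prevalences
#'
#' Group g is consumed when its latent Gaussian exceeds \eqn{\tau_g};
#' \eqn{\tau_g} is the upper-tail standard-normal quantile at the target
#' prevalence, so \eqn{P(Z > \tau_g) = \pi_g}. A prevalence of 1 gives
#' \code{-Inf} (always consumed).
#'
#' @param prevalence numeric vector in (0, 1].
#' @return thresholds, same names as \code{prevalence}.
#' @export
thresholdsFromPrevalence <- function(prevalence) {
    if (any(prevalence <= 0 | prevalence > 1))
        stop("prevalence must be in (0, 1]")
    qnorm(1 - prevalence)
}

#' Plant the study's latent models
#'
#' One sparse precision matrix per (meal type, stratum) for the low and
#' high strata; the mid stratum uses the elementwise average of the low
#' and high precisions (positive definite by convexity), mimicking an
#' intermediate diet-quality pattern.
#'
#' @param config generator config (see \code{\link{defaultGeneratorConfig}}).
#' @param seed base seed; per-model seeds are derived deterministically.
#' @return nested list \code{planted[[stratum]][[mealType]]}.
#' @export
plantStudyModels <- function(config, seed = 1L) {
    p <- length(config$groups)
    planted <- list()
    for (si in seq_along(c("low", "high"))) {
        st <- c("low", "high")[si]
        planted[[st]] <- list()
        for (mi in seq_along(config$mealTypes)) {
            mt <- config$mealTypes[mi]
            planted[[st]][[mt]] <- generateSparsePrecision(
                p, config$sparsity, config$strength,
                seed = seed + 1000L * si + mi,
                maxDegree = config$maxDegree)
        }
    }
    if ("mid" %in% config$strata) {
        planted$mid <- lapply(config$mealTypes, function(mt) {
            Theta <- (planted$low[[mt]]$Theta + planted$high[[mt]]$Theta) / 2
            Sigma <- solve(Theta)
            Sigma <- Sigma / tcrossprod(sqrt(diag(Sigma)))
            pcor <- -Theta / tcrossprod(sqrt(diag(Theta))); diag(pcor) <- 1
            list(Theta = Theta, Sigma = Sigma,
                 support = Theta != 0 & !diag(nrow(Theta)), pcor = pcor)
        })
        names(planted$mid) <- config$mealTypes
    }
    planted
}

# draw one batch of meals for a (stratum, meal type): returns n x p grams
.drawMeals <- function(n, planted, tau, U, pidIdx, config) {
    p <- ncol(U)
    L <- chol(planted$Sigma)
    E <- matrix(rnorm(n * p), n, p) %*% L
    Z <- sqrt(config$rho_b) * U[pidIdx, , drop = FALSE] +
        sqrt(1 - config$rho_b) * E
    consumed <- sweep(Z, 2L, tau, ">")
    amounts <- exp(sweep(sweep(Z, 2L, config$logSd, "*"),
                         2L, config$logMean, "+"))
    amounts * consumed
}

#' Simulate a meal-level dietary-recall cohort
#'
#' Generates item-level recall records with the statistical structure the
#' network analysis assumes: a planted sparse latent precision matrix per
#' meal type and stratum, single-hurdle zero inflation (occurrence and
#' amount driven by one latent Gaussian), equicorrelated participant
#' effects on the latent scale (share \code{rho_b}), lognormal amounts,
#' and per-recall energy derived from per-group energy densities so the
#' plausibility filter is exercisable. Occasion labels include
#' \code{supper} (analysed as dinner) and occasional \code{just_a_drink} /
#' \code{just_a_supplement} occasions to exercise label policies.
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   tables.
#' @param config see \code{\link{defaultGeneratorConfig}}.
#' @return list: \code{records} (item-level data.frame in
#'   \code{\link{loadRecalls}} format), \code{scores} (per-participant
#'   diet-quality totals with true stratum), \code{taxonomy}, and
#'   \code{truth} (planted models, thresholds, rho_b, config).
#' @export
simulateCohort <- function(seed = 1L, config = defaultGeneratorConfig()) {
    planted <- plantStudyModels(config, seed)
    set.seed(seed)
    p <- length(config$groups)
    tau <- thresholdsFromPrevalence(config$prevalence)
    codes <- setNames(rep(config$groups, each = 2L),
                      paste0("FC", rep(sprintf("%02d", seq_len(p)), each = 2L),
                             c("A", "B")))
    taxonomy <- makeTaxonomy(codes, config$groups)
    codeA <- names(codes)[seq(1L, 2L * p, by = 2L)]
    codeB <- names(codes)[seq(2L, 2L * p, by = 2L)]

    # enumerate participants, recalls, occasions
    occ <- list(); scores <- list()
    for (st in config$strata) {
        pid <- sprintf("%s%03d", toupper(substr(st, 1L, 1L)),
                       seq_len(config$nParticipants))
        scores[[st]] <- data.frame(
            participant_id = pid,
            total = pmin(100, pmax(0, rnorm(length(pid),
                config$heiMeans[[st]], config$heiSd))),
            true_stratum = st, stringsAsFactors = FALSE)
        for (i in seq_along(pid)) {
            done <- runif(3L) <= config$recallProb
            for (tri in which(done)) {
                nsnack <- sample(as.integer(names(config$snackCountProb)),
                                 1L, prob = config$snackCountProb)
                labs <- c("breakfast", "lunch",
                          if (runif(1L) < config$supperProb) "supper"
                          else "dinner",
                          rep("snack", nsnack))
                if (runif(1L) < config$drinkOccasionProb)
                    labs <- c(labs, "just_a_drink")
                supp <- runif(1L) < config$supplementOccasionProb
                occ[[length(occ) + 1L]] <- data.frame(
                    participant_id = pid[i],
                    recall_id = paste0(pid[i], "_R", tri),
                    trimester = tri,
                    occasion_index = seq_len(length(labs) + supp),
                    occasion_label = c(labs,
                                       if (supp) "just_a_supplement"),
                    stratum = st, stringsAsFactors = FALSE)
            }
        }
    }
    occ <- do.call(rbind, occ)
    scores <- do.call(rbind, c(scores, make.row.names = FALSE))
    occ$meal_type <- normalizeMealType(occ$occasion_label, quiet = TRUE)

    # participant latent effects
    pids <- unique(occ$participant_id)
    U <- matrix(rnorm(length(pids) * p), length(pids), p,
                dimnames = list(pids, config$groups))

    # draw grams batchwise per (stratum, meal type)
    grams <- matrix(0, nrow(occ), p, dimnames = list(NULL, config$groups))
    for (st in config$strata) for (mt in config$mealTypes) {
        rows <- which(occ$stratum == st & !is.na(occ$meal_type) &
                      occ$meal_type == mt)
        if (!length(rows)) next
        grams[rows, ] <- .drawMeals(length(rows), planted[[st]][[mt]], tau,
                                    U, match(occ$participant_id[rows], pids),
                                    config)
    }
    # supplement occasions: one token item so the label policy is exercised
    suppRows <- which(occ$occasion_label == "just_a_supplement")
    grams[suppRows, p] <- 5

    # explode into item-level records; a consumed group becomes 1 item
    # (code A), split across codes A/B for even occasion indices
    idx <- which(grams > 0, arr.ind = TRUE)
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    g <- idx[, 2L]; m <- idx[, 1L]
    amt <- grams[idx]
    split2 <- occ$occasion_index[m] %% 2L == 0L
    rec1 <- data.frame(occ[m, c("participant_id", "recall_id", "trimester",
                                "occasion_index", "occasion_label")],
                       food_code = ifelse(split2, codeA[g], codeA[g]),
                       amount_g = ifelse(split2, amt / 2, amt),
                       stringsAsFactors = FALSE)
    rec2 <- data.frame(occ[m[split2], c("participant_id", "recall_id",
                                        "trimester", "occasion_index",
                                        "occasion_label")],
                       food_code = codeB[g[split2]],
                       amount_g = amt[split2] / 2,
                       stringsAsFactors = FALSE)
    records <- rbind(rec1, rec2)
    gAll <- c(g, g[split2])
    records$energy_kcal <- records$amount_g *
        unname(config$energyDensity[config$groups[gAll]])
    records <- records[order(records$participant_id, records$recall_id,
                             records$occasion_index, records$food_code), ]
    rownames(records) <- NULL
    records$amount_g <- round(records$amount_g, 3L)
    records$energy_kcal <- round(records$energy_kcal, 3L)

    list(records = records, scores = scores, taxonomy = taxonomy,
         truth = list(planted = planted, tau = tau, rho_b = config$rho_b,
                      config = config, seed = seed))
}

#' Write a simulated cohort to disk
#'
#' Writes the record and score tables as TSV and the truth bundle (planted
#' precision matrices as TSV, thresholds, config echo as YAML) under
#' \code{dir}; the record table is a drop-in input to
#' \code{\link{loadRecalls}}.
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(records = file.path(dir, "recall_records.tsv"),
               scores = file.path(dir, "diet_quality_scores.tsv"),
               taxonomy = file.path(dir, "taxonomy.tsv"),
               config = file.path(dir, "generator_config.yaml"))
    .writeTSV(cohort$records, paths["records"])
    .writeTSV(cohort$scores, paths["scores"])
    .writeTSV(data.frame(food_code = names(cohort$taxonomy$map),
                         group = unname(cohort$taxonomy$map)),
              paths["taxonomy"])
    for (st in names(cohort$truth$planted))
        for (mt in names(cohort$truth$planted[[st]])) {
            f <- file.path(dir, sprintf("planted_precision_%s_%s.tsv",
                                        st, mt))
            m <- cohort$truth$planted[[st]][[mt]]$Theta
            dimnames(m) <- list(cohort$truth$config$groups,
                                cohort$truth$config$groups)
            .writeTSV(data.frame(group = rownames(m), m,
                                 check.names = FALSE), f)
            paths[paste("planted", st, mt, sep = "_")] <- f
        }
    cfg <- cohort$truth$config
    cfg$seed <- cohort$truth$seed
    yaml::write_yaml(lapply(cfg, function(x)
        if (is.numeric(x) || is.integer(x)) unname(x) else x),
        paths["config"])
    invisible(paths)
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
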