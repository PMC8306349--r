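randomCor <- function(p, n = 40L) {
    A <- matrix(rnorm(n * p), n, p)
    cor(A)
}

test_that("unpenalized fit is the inverse correlation", {
    set.seed(1)
    R <- randomCor(4L)
    fit <- graphicalLasso(R, 0)
    expect_lt(max(abs(fit$Theta - solve(R))), 1e-6)
    expect_true(fit$converged)
})

test_that("penalty above max off-diagonal empties the edge set", {
    set.seed(2)
    for (i in 1:20) {
        R <- randomCor(sample(3:6, 1L))
        lam <- max(abs(R[upper.tri(R)]))
        fit <- graphicalLasso(R, lam + 1e-9)
        off <- fit$Theta; diag(off) <- 0
        expect_identical(unname(off), matrix(0, ncol(R), ncol(R)))
        # KKT: the diagonal solution is exactly 1/diag(R)
        expect_equal(unname(diag(fit$Theta)), 1 / diag(R))
    }
})

test_that("coordinate solver matches proximal-gradient oracle", {
    set.seed(3)
    for (i in 1:10) {
        R <- randomCor(3L)
        fit <- graphicalLasso(R, 0.1)
        expect_lt(max(abs(fit$Theta - istaGlasso(R, 0.1))), 1e-4)
    }
    expect_error(graphicalLasso(matrix(c(1, 2, 2, 1), 2L), 0.1),
                 "positive semidefinite")
})

test_that("edge count is nonincreasing in lambda", {
    set.seed(4)
    R <- randomCor(8L, 60L)
    counts <- vapply(defaultLambdaGrid(), function(l) {
        Th <- graphicalLasso(R, l)$Theta
        sum(Th[upper.tri(Th)] != 0)
    }, numeric(1L))
    expect_true(all(diff(counts) <= 0))
})

test_that("CV selection matches a brute-force fold loop and its conventions", {
    pm <- generateSparsePrecision(6L, 0.2, seed = 5L)
    X <- latentMealSample(pm, 200L, prev = 0.8, seed = 6L)
    grid <- c(0.05, 0.15, 0.4)
    cv <- cvSelectLambda(X, grid, k = 5L, seed = 9L)

    # independent re-implementation of the fold loop
    set.seed(9L)
    fold <- sample(rep(1:5, length.out = nrow(X)))
    ll <- matrix(NA_real_, 5L, length(grid))
    for (f in 1:5) {
        Rtr <- rankCorrelationMatrix(X[fold != f, ], zeroVar = "zero")$R
        Rte <- rankCorrelationMatrix(X[fold == f, ], zeroVar = "zero")$R
        for (gi in seq_along(grid)) {
            Th <- graphicalLasso(Rtr, grid[gi])$Theta
            ll[f, gi] <- determinant(Th, TRUE)$modulus - sum(Rte * Th)
        }
    }
    expect_equal(cv$foldLoglik, ll, tolerance = 1e-10)
    expect_equal(cv$lambda, grid[which.max(colMeans(ll))])

    expect_equal(cvSelectLambda(X, 0.2)$lambda, 0.2)  # 1-point grid
    # exact tie in mean loglik -> larger lambda wins
    tied <- cvSelectLambda(X, c(0.3, 0.3))
    expect_equal(tied$lambda, 0.3)
    expect_equal(max(which(tied$meanLoglik == max(tied$meanLoglik))), 2L)
    expect_error(cvSelectLambda(X[1:3, ], grid), "5")
})

test_that("network fitting is deterministic and prunes an independent model", {
    pm <- generateSparsePrecision(8L, 0, seed = 7L)   # diagonal truth
    X <- latentMealSample(pm, 800L, prev = 0.7, seed = 8L)
    me <- mealsFromMatrix(X, "breakfast")
    net1 <- fitMealNetwork(me, "breakfast", "low", seed = 3L)
    net2 <- fitMealNetwork(me, "breakfast", "low", seed = 3L)
    expect_identical(partialCors(net1), partialCors(net2))
    expect_identical(selectedLambda(net1), selectedLambda(net2))
    expect_equal(nrow(edgeTable(net1)), 0L)
    expect_s4_class(net1, "FoodNetwork")
    expect_true(all(abs(partialCors(net1)[upper.tri(diag(8L))]) < 1))
})

test_that("two independent blocks stay unconnected at moderate penalty", {
    set.seed(10)
    pmA <- generateSparsePrecision(4L, 0.5, seed = 11L)
    pmB <- generateSparsePrecision(4L, 0.5, seed = 12L)
    Sigma <- matrix(0, 8L, 8L)
    Sigma[1:4, 1:4] <- pmA$Sigma; Sigma[5:8, 5:8] <- pmB$Sigma
    Z <- matrix(rnorm(4000L * 8L), 4000L) %*% chol(Sigma)
    colnames(Z) <- paste0("g", 1:8)
    R <- rankCorrelationMatrix(Z)$R
    Th <- graphicalLasso(R, 0.1)$Theta
    cross <- Th[1:4, 5:8]
    expect_lte(sum(cross != 0), 1L)     # at most one false cross edge
})

test_that("rank-based fits ignore monotone transforms of any column", {
    pm <- generateSparsePrecision(5L, 0.2, seed = 13L)
    X <- latentMealSample(pm, 150L, prev = 0.9, seed = 14L)
    Y <- X
    Y[, 2L] <- sqrt(Y[, 2L])            # strictly increasing on [0, inf)
    expect_identical(rankCorrelationMatrix(X)$R,
                     rankCorrelationMatrix(Y)$R)
})

test_that("trimester networks reuse the pooled penalty and refilter", {
    cfg <- defaultGeneratorConfig(nParticipants = 30L, nGroups = 8L)
    cfg$strata <- "low"
    co <- simulateCohort(15L, cfg)
    me <- buildMealMatrix(co$records, co$taxonomy)
    x <- subsetMeals(me, mealType = "lunch")
    pooled <- fitMealNetwork(x, "lunch", "low", seed = 2L)
    tri <- fitTrimesterNetworks(x, pooled)
    expect_true(all(vapply(tri, selectedLambda, numeric(1L)) ==
                    selectedLambda(pooled)))
    # a trimester restricted to pooled data reproduces the pooled edges
    same <- fitMealNetwork(x, "lunch", "low",
                           lambda = selectedLambda(pooled))
    expect_identical(edgeTable(same), edgeTable(pooled))
    # trimester with too few meals is skipped with a warning
    xsmall <- x[, seq_len(30L)]
    w <- capture_warnings(fitTrimesterNetworks(xsmall, pooled,
                                               minMeals = 1000L))
    expect_gte(length(w), 1L)
    expect_true(all(grepl("skipped", w)))
})
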