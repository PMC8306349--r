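#' Graphical lasso: L1-penalized sparse precision estimation
#'
#' Maximizes \deqn{\log\det\Theta - \mathrm{tr}(R\Theta) -
#' \lambda \sum_{i \ne j} |\Theta_{ij}|} over symmetric positive-definite
#' matrices, with the penalty on off-diagonal entries only, by block
#' coordinate descent on the covariance estimate (one lasso subproblem per
#' column, solved by coordinate descent with soft-thresholding). Zeros in
#' the solution are exact, so the estimated edge set is read directly off
#' the off-diagonals. At \eqn{\lambda = 0} this is the unpenalized MLE,
#' \eqn{R^{-1}}.
#'
#' @param R correlation (or covariance) matrix; must be PSD — repair with
#'   \code{\link{nearestPSD}} first.
#' @param lambda non-negative L1 penalty.
#' @param tol convergence tolerance on the mean absolute change of the
#'   working covariance per sweep, relative to the mean absolute
#'   off-diagonal of \code{R}.
#' @param maxit maximum outer sweeps.
#' @return list: \code{Theta} (precision), \code{W} (fitted covariance),
#'   \code{iterations}, \code{converged}.
#' @references Friedman, Hastie & Tibshirani (2008) Biostatistics 9(3):
#'   432-441.
#' @export
graphicalLasso <- function(R, lambda, tol = 1e-5, maxit = 200L) {
    p <- ncol(R)
    stopifnot(nrow(R) == p, lambda >= 0)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("R is not positive semidefinite; ",
                              "apply nearestPSD() first")
    if (p == 1L)
        return(list(Theta = matrix(1 / R[1L, 1L], dimnames = dimnames(R)),
                    W = R, iterations = 0L, converged = TRUE))
    W <- R
    diag(W) <- diag(R) + 1e-8   # tiny ridge keeps W11 invertible
    B <- matrix(0, p - 1L, p)   # lasso coefficients per column
    offmean <- mean(abs(R[upper.tri(R)]))
    thresh <- tol * max(offmean, 1e-12)
    converged <- FALSE
    it <- 0L
    while (it < maxit) {
        it <- it + 1L
        delta <- 0
        for (j in seq_len(p)) {
            idx <- setdiff(seq_len(p), j)
            W11 <- W[idx, idx, drop = FALSE]
            s12 <- R[idx, j]
            beta <- B[, j]
            if (lambda == 0) {
                beta <- solve(W11, s12)
            } else {
                # coordinate descent on
                #   1/2 b'W11 b - s12'b + lambda|b|_1
                for (inner in seq_len(100L)) {
                    maxch <- 0
                    for (k in seq_len(p - 1L)) {
                        r <- s12[k] - sum(W11[k, ] * beta) +
                            W11[k, k] * beta[k]
                        bk <- sign(r) * max(abs(r) - lambda, 0) / W11[k, k]
                        maxch <- max(maxch, abs(bk - beta[k]))
                        beta[k] <- bk
                    }
                    if (maxch < 1e-8) break
                }
            }
            w12 <- as.vector(W11 %*% beta)
            delta <- max(delta, max(abs(w12 - W[idx, j])))
            W[idx, j] <- W[j, idx] <- w12
            B[, j] <- beta
        }
        if (delta < thresh) { converged <- TRUE; break }
    }
    if (!converged)
        warning("graphical lasso did not converge in ", maxit,
                " sweeps (last change ", signif(delta, 3), ")")
    # recover Theta from the final (W, B): theta_jj = 1/(w_jj - w12'beta)
    Theta <- matrix(0, p, p, dimnames = dimnames(R))
    for (j in seq_len(p)) {
        idx <- setdiff(seq_len(p), j)
        t22 <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
        Theta[j, j] <- t22
        Theta[idx, j] <- -B[, j] * t22
    }
    Theta <- (Theta + t(Theta)) / 2
    # exact zeros: an entry is an edge only if both column problems kept it
    zero <- (B == 0)
    Z <- matrix(FALSE, p, p)
    for (j in seq_len(p)) Z[setdiff(seq_len(p), j), j] <- zero[, j]
    Theta[Z & t(Z)] <- 0
    list(Theta = Theta, W = W, iterations = it, converged = converged)
}

#' Held-out Gaussian log-likelihood of a precision estimate
#'
#' \eqn{\ell(\Theta; S) = \log\det\Theta - \mathrm{tr}(S\Theta)}, the
#' (scaled, constant-free) Gaussian log-likelihood of held-out data with
#' sample correlation \code{S} under precision \code{Theta}.
#'
#' @param Theta precision matrix.
#' @param S held-out correlation matrix.
#' @return scalar log-likelihood.
#' @export
gaussianLoglik <- function(Theta, S) {
    d <- determinant(Theta, logarithm = TRUE)
    if (d$sign <= 0) return(-Inf)
    as.numeric(d$modulus) - sum(S * Theta)
}

#' Default penalty grid
#'
#' Fifteen log-spaced values on [0.01, 0.6], fixed once for all analyses.
#'
#' @return numeric vector.
#' @export
defaultLambdaGrid <- function() exp(seq(log(0.01), log(0.6),
                                        length.out = 15L))

#' Select the graphical-lasso penalty by k-fold cross-validation
#'
#' Meals are split into \code{k} seeded folds at the meal level (meals are
#' the independent analysis unit). For each candidate \eqn{\lambda} the
#' model is fitted on the training folds' latent correlation and scored by
#' \code{\link{gaussianLoglik}} against the held-out fold's latent
#' correlation (both rank-based and sine-transformed, for consistency with
#' the fitting objective). The \eqn{\lambda} maximizing the mean held-out
#' log-likelihood is selected; ties go to the larger \eqn{\lambda}
#' (sparser model).
#'
#' With many meals the likelihood-optimal penalty is small and keeps
#' numerous near-zero edges (prediction-optimal and selection-optimal
#' penalties diverge); \code{rule = "1se"} — the largest \eqn{\lambda}
#' whose mean held-out log-likelihood is within one standard error of the
#' maximum — is available as a sparser sensitivity option.
#'
#' @param mat meals-by-groups matrix (prevalence-filtered).
#' @param grid candidate penalties (> 0).
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param method rank-correlation method.
#' @param rule \code{"max"} (default: argmax of mean held-out
#'   log-likelihood) or \code{"1se"}.
#' @return list: \code{lambda} (selected), \code{grid}, \code{meanLoglik},
#'   \code{foldLoglik} (k x grid matrix), \code{k}, \code{seed},
#'   \code{rule}.
#' @export
cvSelectLambda <- function(mat, grid = defaultLambdaGrid(), k = 5L,
                           seed = 1L, method = "spearman",
                           rule = c("max", "1se")) {
    rule <- match.arg(rule)
    n <- nrow(mat)
    if (n < k) stop("need at least ", k, " meals for ", k, "-fold CV")
    if (!length(grid) || any(grid <= 0)) stop("grid must be positive")
    grid <- sort(grid)
    set.seed(seed)
    fold <- sample(rep(seq_len(k), length.out = n))
    ll <- matrix(NA_real_, k, length(grid))
    for (f in seq_len(k)) {
        Rtr <- rankCorrelationMatrix(mat[fold != f, , drop = FALSE],
                                     method, zeroVar = "zero")$R
        Rte <- rankCorrelationMatrix(mat[fold == f, , drop = FALSE],
                                     method, zeroVar = "zero")$R
        for (gi in seq_along(grid))
            ll[f, gi] <- gaussianLoglik(
                graphicalLasso(Rtr, grid[gi])$Theta, Rte)
    }
    m <- colMeans(ll)
    best <- max(which(m >= max(m) - 1e-12))   # ties -> larger lambda
    if (rule == "1se") {
        se <- apply(ll, 2L, sd) / sqrt(k)
        best <- max(which(m >= max(m) - se[which.max(m)]))
    }
    list(lambda = grid[best], grid = grid, meanLoglik = m,
         foldLoglik = ll, k = k, seed = seed, rule = rule)
}

#' Fit the food network for one meal type and stratum
#'
#' The full estimation path for one meal-by-stratum matrix: 5\% prevalence
#' filter, rank-based latent correlation (with PSD repair), 5-fold
#' cross-validated penalty selection, graphical lasso at the selected
#' penalty, and partial-correlation extraction.
#'
#' @param x \linkS4class{MealExperiment} restricted to one meal type and
#'   stratum (see \code{\link{subsetMeals}}).
#' @param mealType,stratum labels stored on the result.
#' @param method rank-correlation method.
#' @param grid penalty grid for CV.
#' @param k CV folds.
#' @param seed CV fold seed.
#' @param lambda optional fixed penalty; skips CV when supplied.
#' @param prevalenceThreshold group-retention threshold (default 0.05).
#' @return a \linkS4class{FoodNetwork}.
#' @export
fitMealNetwork <- function(x, mealType = "", stratum = "",
                           method = "spearman", grid = defaultLambdaGrid(),
                           k = 5L, seed = 1L, lambda = NULL,
                           prevalenceThreshold = 0.05) {
    xf <- prevalenceFilter(x, prevalenceThreshold)
    excluded <- S4Vectors::metadata(xf)$excluded_groups
    mat <- mealMatrix(xf)
    if (ncol(mat) < 2L)
        stop("fewer than 2 food groups retained for ", mealType, "/",
             stratum)
    cv <- list()
    if (is.null(lambda)) {
        cv <- cvSelectLambda(mat, grid, k, seed, method)
        lambda <- cv$lambda
    }
    est <- rankCorrelationMatrix(mat, method)
    fit <- graphicalLasso(est$R, lambda)
    prev <- colMeans(mat > 0)
    .networkFromPrecision(fit$Theta, prevalence = prev, lambda = lambda,
                          nMeals = nrow(mat), method = method,
                          excluded = excluded, cv = cv,
                          mealType = mealType, stratum = stratum)
}

#' Trimester-specific networks reusing the pooled penalty
#'
#' For each trimester with enough meals, the 5\% prevalence filter is
#' re-applied on that trimester's meals and the graphical lasso is
#' refitted at the pooled network's selected penalty (no new CV).
#' Trimesters below \code{minMeals} are skipped with a warning.
#'
#' @param x \linkS4class{MealExperiment} for one meal type and stratum
#'   (all trimesters).
#' @param pooled the pooled \linkS4class{FoodNetwork} for the same meal
#'   type and stratum.
#' @param minMeals minimum meals per trimester (default 20).
#' @return named list of \linkS4class{FoodNetwork} per trimester.
#' @export
fitTrimesterNetworks <- function(x, pooled, minMeals = 20L) {
    out <- list()
    for (tri in 1:3) {
        xt <- subsetMeals(x, trimester = tri)
        if (ncol(xt) < minMeals) {
            warning("trimester ", tri, ": only ", ncol(xt),
                    " meals; skipped")
            next
        }
        out[[as.character(tri)]] <- fitMealNetwork(
            xt, mealType = pooled@mealType,
            stratum = paste0(pooled@stratum, "_T", tri),
            method = pooled@method, lambda = pooled@lambda)
    }
    out
}
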