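#' Sine transforms from rank correlations to latent correlations
#'
#' Under a Gaussian copula, the population Spearman and Kendall rank
#' correlations are smooth functions of the latent Pearson correlation;
#' inverting them gives consistent latent-correlation estimates that are
#' invariant to monotone marginal transforms:
#' \deqn{r = 2 \sin(\pi \rho_s / 6), \qquad r = \sin(\pi \tau / 2).}
#' Both maps are odd and send 0 to 0 and 1 to 1.
#'
#' @param rho,tau rank correlations in [-1, 1].
#' @return latent correlation in [-1, 1].
#' @export
spearmanToLatent <- function(rho) {
    if (any(abs(rho) > 1)) stop("Spearman rho must be in [-1, 1]")
    2 * sin(pi * rho / 6)
}

#' @rdname spearmanToLatent
#' @export
kendallToLatent <- function(tau) {
    if (any(abs(tau) > 1)) stop("Kendall tau must be in [-1, 1]")
    sin(pi * tau / 2)
}

#' Latent correlation matrix from meal-level ranks
#'
#' Pairwise Spearman (midranks for ties, the natural treatment for the
#' massive ties at zero intake) or Kendall tau-b correlations, mapped
#' entrywise through the matching sine transform, diagonal forced to 1,
#' then projected to the positive-semidefinite cone by
#' \code{\link{nearestPSD}} if needed (the transformed matrix need not be
#' PSD).
#'
#' @param mat meals-by-groups numeric matrix (use
#'   \code{\link{mealMatrix}}).
#' @param method \code{"spearman"} (default) or \code{"kendall"}.
#' @param zeroVar what to do with a zero-variance column: \code{"error"}
#'   (default; should be impossible after the prevalence filter unless all
#'   values are equal) or \code{"zero"} (correlation 0 with every other
#'   column, used inside CV folds).
#' @return list: \code{R} (latent correlation), \code{method}, \code{n},
#'   \code{repaired} (logical), \code{adjustment} (spectral-norm change of
#'   the repair).
#' @export
rankCorrelationMatrix <- function(mat, method = c("spearman", "kendall"),
                                  zeroVar = c("error", "zero")) {
    method <- match.arg(method)
    zeroVar <- match.arg(zeroVar)
    if (ncol(mat) < 2L) stop("need at least 2 food groups")
    if (nrow(mat) < 3L) stop("need at least 3 meals")
    novar <- apply(mat, 2L, function(x) all(x == x[1L]))
    if (any(novar) && zeroVar == "error")
        stop("zero-variance group(s): ",
             paste(colnames(mat)[novar], collapse = ", "))
    sub <- mat[, !novar, drop = FALSE]
    rho <- cor(sub, method = method)
    R0 <- if (method == "spearman") spearmanToLatent(rho)
          else kendallToLatent(rho)
    R <- diag(ncol(mat))
    dimnames(R) <- list(colnames(mat), colnames(mat))
    R[!novar, !novar] <- R0
    diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    repaired <- min(ev) < 1e-6
    adj <- 0
    if (repaired) {
        R2 <- nearestPSD(R)
        adj <- max(abs(R2 - R))
        R <- R2
    }
    list(R = R, method = method, n = nrow(mat), repaired = repaired,
         adjustment = adj)
}

#' Project a symmetric matrix to the PSD cone with unit diagonal
#'
#' Eigenvalues are clipped at \code{eps}, the matrix is reconstructed and
#' rescaled back to unit diagonal. A no-op when the input already has
#' minimum eigenvalue at or above \code{eps}.
#'
#' @param R symmetric matrix.
#' @param eps eigenvalue floor (default 1e-6).
#' @return repaired matrix with min eigenvalue >= eps (up to rescaling)
#'   and unit diagonal.
#' @export
nearestPSD <- function(R, eps = 1e-6) {
    if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= eps)
        return(R)
    R2 <- R
    for (pass in seq_len(20L)) {       # rescaling can nudge eigenvalues;
        e <- eigen(R2, symmetric = TRUE)   # iterate clip + rescale
        if (min(e$values) >= eps) break
        v <- pmax(e$values, 2 * eps)
        R2 <- e$vectors %*% (v * t(e$vectors))
        d <- sqrt(diag(R2))
        R2 <- R2 / tcrossprod(d)
        R2 <- (R2 + t(R2)) / 2
        diag(R2) <- 1
    }
    dimnames(R2) <- dimnames(R)
    R2
}
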