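#' Chi-square test of node prevalence between strata
#'
#' Pearson chi-square (1 df, no continuity correction by default — a
#' Yates-corrected variant is available) on the 2x2 table of consumed /
#' not-consumed meals by stratum, testing whether a food group's node
#' size (percentage of meals in which it was consumed) differs between
#' the low and high diet-quality strata. When an expected cell is zero
#' (e.g. the group was never consumed in either stratum, or always
#' consumed in both) the test is undefined and reported as NA.
#'
#' @param n1,k1 meals and consuming meals in stratum 1.
#' @param n2,k2 meals and consuming meals in stratum 2.
#' @param correct apply Yates continuity correction (default FALSE).
#' @param alpha significance level for the flag (default 0.05).
#' @return one-row data.frame: counts, proportions, \code{statistic},
#'   \code{p_value}, \code{significant}.
#' @export
chiSquarePrevalenceTest <- function(n1, k1, n2, k2, correct = FALSE,
                                    alpha = 0.05) {
    stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        stat <- NA_real_; pval <- NA_real_
    } else {
        ht <- suppressWarnings(chisq.test(tab, correct = correct))
        stat <- unname(ht$statistic); pval <- unname(ht$p.value)
    }
    data.frame(n1 = n1, k1 = k1, n2 = n2, k2 = k2,
               prop1 = k1 / n1, prop2 = k2 / n2,
               statistic = stat, p_value = pval,
               significant = !is.na(pval) & pval < alpha)
}

#' Cross-stratum node-prevalence comparison for one meal type
#'
#' Per food group: meal counts, consuming-meal counts and proportions in
#' each stratum, and the chi-square test of
#' \code{\link{chiSquarePrevalenceTest}}. Meal counts are the denominator
#' (node size is the percentage of meals in which the food was consumed).
#' No multiple-testing adjustment is applied by default; set
#' \code{adjust = "BH"} for Benjamini-Hochberg adjusted significance.
#'
#' @param xA,xB \linkS4class{MealExperiment}s for the two strata (same
#'   food-group rows), already restricted to one meal type.
#' @param labels stratum labels, length 2.
#' @param correct,alpha passed to \code{\link{chiSquarePrevalenceTest}}.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame, one row per food group.
#' @export
prevalenceComparison <- function(xA, xB, labels = c("low", "high"),
                                 correct = FALSE, alpha = 0.05,
                                 adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    stopifnot(identical(rownames(xA), rownames(xB)))
    gA <- SummarizedExperiment::assay(xA, "grams")
    gB <- SummarizedExperiment::assay(xB, "grams")
    out <- do.call(rbind, lapply(rownames(gA), function(g) {
        r <- chiSquarePrevalenceTest(ncol(gA), sum(gA[g, ] > 0),
                                     ncol(gB), sum(gB[g, ] > 0),
                                     correct = correct, alpha = alpha)
        cbind(data.frame(group = g, stringsAsFactors = FALSE), r)
    }))
    names(out)[match(c("n1", "k1", "n2", "k2", "prop1", "prop2"),
                     names(out))] <-
        c(paste0("n_", labels[1L]), paste0("k_", labels[1L]),
          paste0("n_", labels[2L]), paste0("k_", labels[2L]),
          paste0("prop_", labels[1L]), paste0("prop_", labels[2L]))
    if (adjust == "BH") {
        out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
        out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
    }
    rownames(out) <- NULL
    out
}
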