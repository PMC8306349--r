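#' Load diet-quality (HEI-style) component scoring standards
#'
#' The Healthy Eating Index-2015 has 13 components — 9 adequacy and 4
#' moderation — each scored from an energy-adjusted density (amount per
#' 1000 kcal or percent of energy) against a pair of standards, and summed
#' to a maximum of 100. The standards themselves are configuration, not
#' code: this reads the required table. An example file with the
#' HEI-2015 values is shipped at
#' \code{system.file("extdata", "hei2015_standards_example.tsv",
#' package = "mealnets")}; users should verify it against their own
#' scoring documentation before substantive use.
#'
#' Columns: \code{component}, \code{type} (adequacy/moderation),
#' \code{unit} (\code{per_1000kcal} or \code{percent_energy}),
#' \code{standard_zero} (density scoring 0 points),
#' \code{standard_max} (density scoring maximum points),
#' \code{max_points}.
#'
#' @param path TSV of standards; default is the shipped example.
#' @return validated data.frame of standards.
#' @export
loadHEIStandards <- function(path = system.file("extdata",
        "hei2015_standards_example.tsv", package = "mealnets")) {
    st <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("component", "type", "unit", "standard_zero", "standard_max",
              "max_points")
    missing <- setdiff(need, colnames(st))
    if (length(missing))
        stop("standards file is missing column(s): ",
             paste(missing, collapse = ", "))
    validateHEIStandards(st)
    st
}

#' @rdname loadHEIStandards
#' @param standards a standards data.frame to validate.
#' @export
validateHEIStandards <- function(standards) {
    if (nrow(standards) != 13L)
        stop("expected 13 components, got ", nrow(standards))
    if (sum(standards$type == "adequacy") != 9L ||
        sum(standards$type == "moderation") != 4L)
        stop("expected 9 adequacy and 4 moderation components")
    if (sum(standards$max_points) != 100)
        stop("maximum points must sum to 100")
    bad <- standards$type == "adequacy" &
        standards$standard_zero >= standards$standard_max
    if (any(bad))
        stop("adequacy standard_zero must be below standard_max for: ",
             paste(standards$component[bad], collapse = ", "))
    bad <- standards$type == "moderation" &
        standards$standard_zero <= standards$standard_max
    if (any(bad))
        stop("moderation standard_zero must exceed standard_max for: ",
             paste(standards$component[bad], collapse = ", "))
    invisible(TRUE)
}

#' Score one diet-quality component from its energy-adjusted density
#'
#' Adequacy components score 0 at or below the zero-point standard,
#' maximum points at or above the max standard, linearly in between.
#' Moderation components score maximum points at or below their (lower)
#' max standard and 0 at or beyond the (higher) zero-point standard,
#' linearly in between. Results are clipped to [0, max_points].
#'
#' @param density non-negative energy-adjusted intake density.
#' @param standard one row of the standards table.
#' @return points in [0, standard$max_points].
#' @export
heiComponentScore <- function(density, standard) {
    stopifnot(all(density >= 0))
    z <- standard$standard_zero
    m <- standard$standard_max
    if (standard$type == "adequacy") {
        if (z >= m) stop("malformed adequacy standard for ",
                         standard$component)
        frac <- (density - z) / (m - z)
    } else {
        if (z <= m) stop("malformed moderation standard for ",
                         standard$component)
        frac <- (z - density) / (z - m)
    }
    standard$max_points * pmin(1, pmax(0, frac))
}

#' Pooled diet-quality score per participant
#'
#' Recalls are pooled across pregnancy ("simple scoring, per person"):
#' component amounts and energy are summed over all of a participant's
#' plausible recalls first, densities are computed from those pooled sums
#' (amount per 1000 kcal, or percent of energy for \code{percent_energy}
#' components), and component scores are then summed. This differs from
#' averaging per-recall scores whenever scoring saturates.
#'
#' @param components data.frame with one row per (participant, recall,
#'   component): columns \code{participant_id}, \code{recall_id},
#'   \code{component}, \code{amount} (component units: cup/oz equivalents,
#'   grams, or kcal for \code{percent_energy} components) and
#'   \code{energy_kcal} (total recall energy, repeated across the recall's
#'   rows).
#' @param standards standards table (see \code{\link{loadHEIStandards}}).
#' @return data.frame: \code{participant_id}, one column per component
#'   score, and \code{total}.
#' @export
heiTotalPooled <- function(components, standards) {
    validateHEIStandards(standards)
    need <- c("participant_id", "recall_id", "component", "amount",
              "energy_kcal")
    missing <- setdiff(need, colnames(components))
    if (length(missing))
        stop("component table missing column(s): ",
             paste(missing, collapse = ", "))
    out <- lapply(split(components, components$participant_id), function(d) {
        recalls <- d[!duplicated(d$recall_id),
                     c("recall_id", "energy_kcal")]
        energy <- sum(recalls$energy_kcal)
        if (energy <= 0) stop("zero pooled energy for participant ",
                              d$participant_id[1L])
        amounts <- tapply(d$amount, d$component, sum)
        scores <- vapply(seq_len(nrow(standards)), function(i) {
            st <- standards[i, ]
            amt <- amounts[st$component]
            if (is.na(amt)) amt <- 0
            dens <- if (st$unit == "percent_energy")
                100 * amt / energy else 1000 * amt / energy
            heiComponentScore(dens, st)
        }, numeric(1L))
        c(scores, total = sum(scores))
    })
    res <- data.frame(participant_id = names(out),
                      do.call(rbind, out), check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
    colnames(res) <- c("participant_id", standards$component, "total")
    res
}

#' Assign diet-quality tertiles
#'
#' Participants are ranked by total score and split into three groups as
#' equal as possible; when sizes cannot be equal, the extra member(s) go
#' to the low tertile before mid before high. Ties in score are broken by
#' participant id (stable, documented). The low and high tertiles are the
#' strata used for network analysis.
#'
#' @param scores data.frame with \code{participant_id} and \code{total}.
#' @return \code{scores} with a \code{tertile} factor
#'   (\code{low}/\code{mid}/\code{high}).
#' @export
assignTertiles <- function(scores) {
    n <- nrow(scores)
    if (n < 3L) stop("need at least 3 participants for tertiles")
    if (length(unique(scores$total)) == 1L)
        warning("all diet-quality scores identical; ",
                "tertiles assigned by participant-id order")
    ord <- order(scores$total, scores$participant_id)
    sizes <- rep(n %/% 3L, 3L)
    extra <- n %% 3L
    if (extra >= 1L) sizes[1L] <- sizes[1L] + 1L   # low first
    if (extra == 2L) sizes[2L] <- sizes[2L] + 1L
    lab <- rep(c("low", "mid", "high"), times = sizes)
    scores$tertile <- factor(NA, levels = c("low", "mid", "high"))
    scores$tertile[ord] <- lab
    scores
}
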