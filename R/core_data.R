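#' Read dietary recall records
#'
#' Reads a delimited file of 24-h-recall-style food item records, one row
#' per item eaten: participant, recall, trimester, eating-occasion label
#' and order, food code, grams and kcal. Rows violating the row-level
#' contracts (negative amounts or energy, trimester outside 1..3) are
#' rejected with their row indices reported in a warning and in the
#' \code{"rejected"} attribute; nothing is dropped silently.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field separator; default tab.
#' @return data.frame of recall records with columns \code{participant_id},
#'   \code{recall_id}, \code{trimester}, \code{occasion_index},
#'   \code{occasion_label}, \code{food_code}, \code{amount_g},
#'   \code{energy_kcal}; attribute \code{"rejected"} holds indices of
#'   rejected input rows.
#' @export
loadRecalls <- function(path, sep = "\t") {
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                     check.names = FALSE)
    need <- c("participant_id", "recall_id", "trimester", "occasion_index",
              "occasion_label", "food_code", "amount_g", "energy_kcal")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("recall file is missing required column(s): ",
             paste(missing, collapse = ", "))
    df <- df[, need]
    bad <- which(!is.finite(df$amount_g) | df$amount_g < 0 |
                 !is.finite(df$energy_kcal) | df$energy_kcal < 0 |
                 !df$trimester %in% 1:3 | df$occasion_index < 1)
    if (length(bad)) {
        warning("rejected ", length(bad), " invalid row(s): ",
                paste(head(bad, 20L), collapse = ", "),
                if (length(bad) > 20L) ", ...")
        df <- df[-bad, , drop = FALSE]
    }
    df$participant_id <- as.character(df$participant_id)
    df$recall_id <- as.character(df$recall_id)
    df$food_code <- as.character(df$food_code)
    rownames(df) <- NULL
    attr(df, "rejected") <- bad
    df
}

#' Energy-plausibility filter on recalls
#'
#' Recalls totalling under 600 kcal are treated as implausible and
#' excluded; recalls over 4500 kcal are retained but flagged for manual
#' review (pregnancy raises energy requirements, so high totals are
#' considered plausible); everything in between is retained unflagged.
#'
#' @param records recall records (as from \code{\link{loadRecalls}}).
#' @param low exclusion threshold in kcal (default 600).
#' @param high review-flag threshold in kcal (default 4500).
#' @return list with \code{retained}, \code{excluded} (records data.frames)
#'   and \code{flagged} (character recall ids among the retained whose
#'   total exceeds \code{high}); plus a \code{totals} data.frame of
#'   per-recall energy.
#' @export
filterEnergyPlausibility <- function(records, low = 600, high = 4500) {
    key <- paste(records$participant_id, records$recall_id, sep = "\r")
    tot <- tapply(records$energy_kcal, key, sum)
    excl <- names(tot)[tot < low]
    flag <- names(tot)[tot > high]
    keep <- !(key %in% excl)
    totals <- data.frame(
        participant_id = sub("\r.*", "", names(tot)),
        recall_id = sub(".*\r", "", names(tot)),
        energy_kcal = as.numeric(tot),
        status = ifelse(tot < low, "excluded",
                        ifelse(tot > high, "flagged", "retained")),
        stringsAsFactors = FALSE, row.names = NULL)
    list(retained = records[keep, , drop = FALSE],
         excluded = records[!keep, , drop = FALSE],
         flagged = sub(".*\r", "", flag),
         totals = totals)
}

.mealTypePolicy <- function(policy = list()) {
    default <- list(breakfast = "breakfast", brunch = "lunch",
                    lunch = "lunch", dinner = "dinner", supper = "dinner",
                    snack = "snack", just_a_drink = "snack",
                    just_a_supplement = "drop")
    default[names(policy)] <- policy
    default
}

#' Map eating-occasion labels to network meal types
#'
#' Occasions labelled \emph{supper} are analysed as dinner. Labels the
#' network analysis does not use directly are mapped by a configurable
#' policy (defaults: brunch to lunch, just_a_drink to snack,
#' just_a_supplement dropped). Each mapping applied is reported via
#' \code{message} so the policy in force is visible in logs.
#'
#' @param labels character vector of occasion labels.
#' @param policy named list overriding the default label policy; map a
#'   label to \code{"drop"} to remove those occasions.
#' @param quiet suppress the mapping log.
#' @return character vector of \code{breakfast/lunch/dinner/snack} or
#'   \code{NA} for dropped occasions.
#' @export
normalizeMealType <- function(labels, policy = list(), quiet = FALSE) {
    pol <- .mealTypePolicy(policy)
    unknown <- setdiff(unique(labels), names(pol))
    if (length(unknown))
        stop("unknown occasion label(s): ", paste(unknown, collapse = ", "))
    out <- unlist(pol)[labels]
    if (!quiet) {
        changed <- unique(labels[labels != out | out == "drop"])
        for (lb in changed)
            message("occasion '", lb, "' -> ", pol[[lb]])
    }
    out <- unname(out)
    out[out == "drop"] <- NA_character_
    out
}

#' Load a food-code to food-group taxonomy
#'
#' The taxonomy is a user-supplied mapping from food codes to food-group
#' names (the analysis default is a 40-group scheme). Mixed-dish handling
#' is expressed entirely through this mapping: a code for a composite food
#' simply maps to whichever group best represents it.
#'
#' @param path TSV with columns \code{food_code}, \code{group}.
#' @param groups optional ordered character vector of all group names;
#'   defaults to unique groups in file order.
#' @return list with \code{map} (named character, code -> group) and
#'   \code{groups} (ordered group names).
#' @export
loadTaxonomy <- function(path, groups = NULL) {
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    missing <- setdiff(c("food_code", "group"), colnames(df))
    if (length(missing))
        stop("taxonomy file is missing column(s): ",
             paste(missing, collapse = ", "))
    makeTaxonomy(setNames(as.character(df$group), as.character(df$food_code)),
                 groups)
}

#' @rdname loadTaxonomy
#' @param map named character vector, names are food codes, values groups.
#' @export
makeTaxonomy <- function(map, groups = NULL) {
    if (anyDuplicated(names(map)))
        stop("taxonomy maps some food code more than once")
    if (is.null(groups)) groups <- unique(unname(map))
    if (anyDuplicated(groups)) stop("duplicate group names")
    if (!all(map %in% groups))
        stop("taxonomy contains groups absent from the group list")
    list(map = map, groups = groups)
}

#' Build the meal-by-food-group intake matrix
#'
#' Aggregates item-level gram intakes into one row per eating occasion and
#' one column per food group (groups never consumed stay as zero columns),
#' and wraps the result in a \linkS4class{MealExperiment} (food groups as
#' rows, meals as columns, Bioconductor orientation). Occasion labels are
#' normalized via \code{\link{normalizeMealType}} first; all meals —
#' including multiple snack occasions within a recall — are kept as
#' separate, independent observations.
#'
#' @param records recall records (plausibility-filtered).
#' @param taxonomy from \code{\link{loadTaxonomy}}/\code{\link{makeTaxonomy}}.
#' @param unmapped policy for food codes absent from the taxonomy:
#'   \code{"error"} (default) or \code{"drop"} (logged).
#' @param mealPolicy occasion-label policy passed to
#'   \code{\link{normalizeMealType}}.
#' @return a \linkS4class{MealExperiment}.
#' @export
buildMealMatrix <- function(records, taxonomy, unmapped = c("error", "drop"),
                            mealPolicy = list()) {
    unmapped <- match.arg(unmapped)
    rec <- records
    rec$meal_type <- normalizeMealType(rec$occasion_label, mealPolicy,
                                       quiet = TRUE)
    rec <- rec[!is.na(rec$meal_type), , drop = FALSE]
    known <- rec$food_code %in% names(taxonomy$map)
    if (!all(known)) {
        codes <- unique(rec$food_code[!known])
        if (unmapped == "error")
            stop("food code(s) not in taxonomy: ",
                 paste(head(codes, 10L), collapse = ", "))
        message("dropping ", sum(!known), " item(s) with unmapped code(s): ",
                paste(head(codes, 10L), collapse = ", "))
        rec <- rec[known, , drop = FALSE]
    }
    if (!nrow(rec)) stop("no records left after mapping")
    rec$group <- unname(taxonomy$map[rec$food_code])
    mealKey <- paste(rec$participant_id, rec$recall_id, rec$meal_type,
                     rec$occasion_index, sep = "\r")
    meals <- unique(mealKey)
    grams <- matrix(0, nrow = length(taxonomy$groups), ncol = length(meals),
                    dimnames = list(taxonomy$groups, NULL))
    gi <- match(rec$group, taxonomy$groups)
    mi <- match(mealKey, meals)
    for (k in seq_len(nrow(rec)))
        grams[gi[k], mi[k]] <- grams[gi[k], mi[k]] + rec$amount_g[k]
    parts <- do.call(rbind, strsplit(meals, "\r", fixed = TRUE))
    cd <- S4Vectors::DataFrame(
        participant_id = parts[, 1L], recall_id = parts[, 2L],
        meal_type = parts[, 3L],
        occasion_index = as.integer(parts[, 4L]),
        trimester = as.integer(rec$trimester[match(meals, mealKey)]))
    colnames(grams) <- paste(parts[, 1L], parts[, 2L], parts[, 3L],
                             parts[, 4L], sep = ".")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(grams = grams), colData = cd)
    new("MealExperiment", se)
}

#' Meal intake matrix in meals-by-groups orientation
#'
#' @param x a \linkS4class{MealExperiment}.
#' @return numeric matrix, rows = meals, columns = food groups.
#' @export
mealMatrix <- function(x) t(SummarizedExperiment::assay(x, "grams"))

#' Subset meals by meal type / stratum / trimester
#'
#' @param x a \linkS4class{MealExperiment}.
#' @param mealType,trimester optional filters on \code{colData}.
#' @param participants optional character vector of participant ids (e.g.
#'   one tertile stratum).
#' @return a \linkS4class{MealExperiment} with the selected meals.
#' @export
subsetMeals <- function(x, mealType = NULL, participants = NULL,
                        trimester = NULL) {
    cd <- SummarizedExperiment::colData(x)
    keep <- rep(TRUE, ncol(x))
    if (!is.null(mealType)) keep <- keep & cd$meal_type %in% mealType
    if (!is.null(participants))
        keep <- keep & cd$participant_id %in% participants
    if (!is.null(trimester)) keep <- keep & cd$trimester %in% trimester
    x[, keep]
}

#' Prevalence filter: drop rarely consumed food groups
#'
#' A food group enters a network only if it was consumed in at least
#' \code{threshold} of the meals; groups consumed on \emph{fewer} than 5\%
#' of meals are excluded (strict inequality: exactly 5\% is retained).
#' This avoids over-representing relationships between episodically
#' consumed foods eaten together on only a few occasions.
#'
#' @param x a \linkS4class{MealExperiment}.
#' @param threshold minimum consumption proportion (default 0.05).
#' @return the filtered \linkS4class{MealExperiment}; excluded group names
#'   in \code{metadata(x)$excluded_groups}.
#' @export
prevalenceFilter <- function(x, threshold = 0.05) {
    if (ncol(x) == 0L) stop("empty meal matrix")
    prev <- rowMeans(SummarizedExperiment::assay(x, "grams") > 0)
    keep <- prev >= threshold
    out <- x[keep, ]
    S4Vectors::metadata(out)$excluded_groups <- rownames(x)[!keep]
    S4Vectors::metadata(out)$prevalence <- prev[keep]
    out
}
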