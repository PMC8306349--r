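#' Two-level ICC: between-participant variance at one meal type
#'
#' Random-intercept model \eqn{y_{mi} = \mu + u_i + e_{mi}} fitted by REML
#' (\pkg{lme4}; variance components are constrained non-negative by
#' construction), with participants as the upper level and meals as
#' observations. \eqn{ICC = \sigma^2_u / (\sigma^2_u + \sigma^2_e)}: the
#' share of intake variation explained by differences between
#' participants at this meal type. A high value means the food's network
#' node reflects a subset of participants (e.g. milk consumers vs
#' non-consumers) rather than the tertile as a whole.
#'
#' @param y numeric intake per meal (grams; zeros included).
#' @param participant participant id per meal.
#' @return list: \code{icc}, \code{var_participant}, \code{var_residual},
#'   \code{n_obs}, \code{flag_high} (\code{icc > 0.30}).
#' @export
fitTwoLevelICC <- function(y, participant) {
    stopifnot(length(y) == length(participant))
    participant <- as.character(participant)
    if (length(unique(participant)) < 2L)
        stop("need at least 2 participants")
    if (all(table(participant) < 2L))
        stop("variance components unidentifiable: ",
             "no participant has repeated observations")
    if (var(y) == 0) {
        warning("all observations identical; ICC set to 0")
        return(list(icc = 0, var_participant = 0, var_residual = 0,
                    n_obs = length(y), flag_high = FALSE))
    }
    fit <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | participant),
                   data = data.frame(y = y, participant = participant),
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                       "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vu <- vc$vcov[vc$grp == "participant"]
    ve <- vc$vcov[vc$grp == "Residual"]
    icc <- vu / (vu + ve)
    list(icc = icc, var_participant = vu, var_residual = ve,
         n_obs = length(y), flag_high = icc > 0.30)
}

#' Three-level ICC: share of intake variation explained by meal type
#'
#' Crossed random-intercept model with participant and meal-type
#' components plus residual,
#' \eqn{y = \mu + u_{participant} + v_{mealtype} + e}, fitted by REML.
#' \eqn{ICC_{mealtype} = \sigma^2_v / (\sigma^2_u + \sigma^2_v +
#' \sigma^2_e)}: how much of a food's intake variation is explained by
#' \emph{which meal} it is (breakfast/lunch/dinner/snack), accounting for
#' between-participant variation. With only four meal-type levels the
#' meal-type variance is weakly identified; treat small differences
#' cautiously.
#'
#' @param y numeric intake per meal.
#' @param participant participant id per meal.
#' @param mealType meal type per meal.
#' @return list: \code{icc}, \code{var_participant}, \code{var_mealtype},
#'   \code{var_residual}, \code{n_obs}, \code{flag_high}.
#' @export
fitThreeLevelICC <- function(y, participant, mealType) {
    stopifnot(length(y) == length(participant),
              length(y) == length(mealType))
    if (length(unique(mealType)) < 2L)
        stop("need at least 2 meal types")
    if (var(y) == 0) {
        warning("all observations identical; ICC set to 0")
        return(list(icc = 0, var_participant = 0, var_mealtype = 0,
                    var_residual = 0, n_obs = length(y),
                    flag_high = FALSE))
    }
    d <- data.frame(y = y, participant = as.character(participant),
                    mealType = as.character(mealType))
    fit <- suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | participant) + (1 | mealType), data = d,
                   REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular =
                       "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    vu <- vc$vcov[vc$grp == "participant"]
    vm <- vc$vcov[vc$grp == "mealType"]
    ve <- vc$vcov[vc$grp == "Residual"]
    icc <- vm / (vu + vm + ve)
    list(icc = icc, var_participant = vu, var_mealtype = vm,
         var_residual = ve, n_obs = length(y), flag_high = icc > 0.30)
}

#' Full ICC table per stratum
#'
#' For each stratum: one three-level ICC per food group (variation
#' explained by meal type) and one two-level ICC per food group and meal
#' type (variation explained by participants), restricted to food groups
#' consumed in at least 5\% of the stratum's modelled meals. ICCs above
#' 0.30 are flagged (strict inequality).
#'
#' @param x a \linkS4class{MealExperiment} (all meal types).
#' @param strata named list mapping stratum label to participant ids; use
#'   \code{list(all = unique(participant ids))} for an unstratified table.
#' @param transform optional intake transform, e.g. \code{log1p}
#'   (sensitivity analysis); default identity.
#' @param prevalenceThreshold group-inclusion threshold (default 0.05).
#' @return data.frame: \code{stratum}, \code{group}, \code{model},
#'   \code{meal_type} (NA for three-level rows), \code{icc}, variance
#'   components, \code{n_obs}, \code{flag_high}.
#' @export
iccTable <- function(x, strata, transform = identity,
                     prevalenceThreshold = 0.05) {
    rows <- list()
    for (st in names(strata)) {
        xs <- subsetMeals(x, participants = strata[[st]])
        if (ncol(xs) == 0L) next
        xs <- prevalenceFilter(xs, prevalenceThreshold)
        cd <- SummarizedExperiment::colData(xs)
        grams <- SummarizedExperiment::assay(xs, "grams")
        for (gname in rownames(grams)) {
            y <- transform(grams[gname, ])
            r3 <- fitThreeLevelICC(y, cd$participant_id, cd$meal_type)
            rows[[length(rows) + 1L]] <- data.frame(
                stratum = st, group = gname, model = "three_level",
                meal_type = NA_character_, icc = r3$icc,
                var_participant = r3$var_participant,
                var_mealtype = r3$var_mealtype,
                var_residual = r3$var_residual,
                n_obs = r3$n_obs, flag_high = r3$flag_high,
                stringsAsFactors = FALSE)
            for (mt in unique(cd$meal_type)) {
                sel <- cd$meal_type == mt
                ymt <- y[sel]
                pid <- cd$participant_id[sel]
                r2 <- tryCatch(
                    suppressWarnings(fitTwoLevelICC(ymt, pid)),
                    error = function(e) NULL)
                if (is.null(r2)) next
                rows[[length(rows) + 1L]] <- data.frame(
                    stratum = st, group = gname, model = "two_level",
                    meal_type = mt, icc = r2$icc,
                    var_participant = r2$var_participant,
                    var_mealtype = NA_real_,
                    var_residual = r2$var_residual,
                    n_obs = r2$n_obs, flag_high = r2$flag_high,
                    stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, rows)
}
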