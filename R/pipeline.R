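#' Default pipeline configuration
#'
#' @param outDir output directory.
#' @param seed master seed: drives simulation (when no input files are
#'   given), CV fold assignment and Louvain sweeps.
#' @return config list for \code{\link{runPipeline}}. Fields of note:
#'   \code{recordsPath}/\code{taxonomyPath}/\code{scoresPath} (input
#'   files; when \code{recordsPath} is NULL a synthetic cohort is
#'   simulated with \code{generator}), \code{method} (rank correlation),
#'   \code{lambdaGrid}, \code{prevalenceThreshold}, \code{mealPolicy}
#'   (occasion-label policy), \code{trimesterNetworks}, \code{icc}
#'   (logical switches), \code{minTrimesterMeals}.
#' @export
defaultPipelineConfig <- function(outDir = tempfile("mealnets_run_"),
                                  seed = 1L) {
    list(outDir = outDir, seed = as.integer(seed),
         recordsPath = NULL, taxonomyPath = NULL, scoresPath = NULL,
         generator = defaultGeneratorConfig(),
         method = "spearman", lambdaGrid = defaultLambdaGrid(),
         prevalenceThreshold = 0.05, mealPolicy = list(),
         energyLow = 600, energyHigh = 4500,
         mealTypes = c("breakfast", "lunch", "dinner", "snack"),
         strata = c("low", "high"),
         trimesterNetworks = TRUE, minTrimesterMeals = 20L,
         icc = TRUE, comparison = TRUE)
}

.countOccasions <- function(records) {
    length(unique(paste(records$participant_id, records$recall_id,
                        records$occasion_index, sep = "\r")))
}

#' Run the full meal-network analysis pipeline
#'
#' Orchestrates the whole analysis: load (or simulate) recall records,
#' apply the energy-plausibility filter, build the meal-level intake
#' matrix, assign diet-quality tertiles, then per meal type and stratum
#' fit the sparse copula network (5\% prevalence filter, rank
#' correlation, 5-fold CV graphical lasso), detect Louvain communities,
#' compute node roles, match communities across strata, and export
#' GraphML + TSV tables; optionally fits trimester-specific networks
#' (reusing each pooled penalty), the ICC variance-decomposition table,
#' and the cross-stratum prevalence comparison. A JSON run manifest
#' records the config echo, seeds, package version, selected penalties,
#' and meal counts through every filtering stage (counts are conserved:
#' occasions in = dropped by energy filter + dropped by label policy +
#' meals in the matrix).
#'
#' @param config list from \code{\link{defaultPipelineConfig}}.
#' @return invisibly, a list with all in-memory results (\code{meals},
#'   \code{scores}, \code{networks}, \code{partitions}, \code{roles},
#'   \code{matching}, \code{trimester}, \code{icc}, \code{comparison},
#'   \code{manifest}).
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
    required <- c("outDir", "seed")
    missing <- required[!required %in% names(config)]
    if (length(missing))
        stop("pipeline config is missing field(s): ",
             paste(missing, collapse = ", "))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    # config echo excludes the output path (and the bulky generator spec)
    # so reruns into different directories stay byte-identical
    manifest <- list(config = config[setdiff(names(config),
                                             c("generator", "outDir"))],
                     package_version =
                         as.character(packageVersion("mealnets")),
                     seed = config$seed)

    # ---- stage: inputs ----
    if (is.null(config$recordsPath)) {
        cohort <- simulateCohort(config$seed, config$generator)
        records <- cohort$records
        taxonomy <- cohort$taxonomy
        scores <- cohort$scores
        manifest$input <- "simulated"
    } else {
        if (is.null(config$taxonomyPath))
            stop("config field taxonomyPath is required with recordsPath")
        if (is.null(config$scoresPath))
            stop("config field scoresPath is required with recordsPath")
        records <- loadRecalls(config$recordsPath)
        taxonomy <- loadTaxonomy(config$taxonomyPath)
        scores <- read.delim(config$scoresPath, sep = "\t",
                             stringsAsFactors = FALSE)
        manifest$input <- config$recordsPath
    }

    # ---- stage: energy plausibility ----
    ef <- filterEnergyPlausibility(records, config$energyLow,
                                   config$energyHigh)
    occIn <- .countOccasions(records)
    occExcl <- .countOccasions(ef$excluded)
    manifest$energy_filter <- list(
        recalls_in = nrow(ef$totals),
        recalls_excluded = sum(ef$totals$status == "excluded"),
        recalls_flagged_high = length(ef$flagged),
        occasions_in = occIn, occasions_excluded = occExcl)

    # ---- stage: meal matrix ----
    meals <- buildMealMatrix(ef$retained, taxonomy,
                             mealPolicy = config$mealPolicy)
    occDropped <- .countOccasions(ef$retained) - ncol(meals)
    manifest$meal_matrix <- list(
        n_meals = ncol(meals), n_groups = nrow(meals),
        occasions_dropped_by_label_policy = occDropped,
        counts_conserved =
            (occIn == occExcl + occDropped + ncol(meals)))

    # ---- stage: tertiles ----
    scores <- assignTertiles(scores)
    strata <- lapply(setNames(config$strata, config$strata), function(st)
        scores$participant_id[scores$tertile == st])
    .writeTSV(scores, file.path(config$outDir, "diet_quality_tertiles.tsv"))
    manifest$tertiles <- lapply(split(scores$participant_id,
                                      scores$tertile), length)

    # ---- stage: networks, communities, roles ----
    networks <- list(); partitions <- list(); roles <- list()
    trimester <- list(); lambdas <- list()
    for (mt in config$mealTypes) for (st in config$strata) {
        key <- paste(mt, st, sep = "_")
        xms <- subsetMeals(meals, mealType = mt,
                           participants = strata[[st]])
        net <- fitMealNetwork(xms, mealType = mt, stratum = st,
                              method = config$method,
                              grid = config$lambdaGrid,
                              seed = config$seed,
                              prevalenceThreshold =
                                  config$prevalenceThreshold)
        g <- buildGraph(net)
        part <- louvainPartition(g, seed = config$seed)
        rl <- nodeRoles(g, part)
        networks[[key]] <- net
        partitions[[key]] <- part
        roles[[key]] <- rl
        lambdas[[key]] <- net@lambda
        if (isTRUE(config$trimesterNetworks))
            trimester[[key]] <- withCallingHandlers(
                fitTrimesterNetworks(xms, net,
                                     config$minTrimesterMeals),
                warning = function(w) invokeRestart("muffleWarning"))
    }
    manifest$lambda <- lambdas
    manifest$networks <- lapply(networks, function(n) list(
        n_meals = n@nMeals, n_groups = length(n@groups),
        n_excluded_groups = length(n@excluded),
        n_edges = nrow(edgeTable(n))))

    # ---- stage: community matching + export ----
    matching <- list()
    for (mt in config$mealTypes) {
        kl <- paste(mt, config$strata[1L], sep = "_")
        kh <- paste(mt, config$strata[2L], sep = "_")
        mtc <- matchCommunities(partitions[[kl]], partitions[[kh]])
        matching[[mt]] <- mtc
        .writeTSV(mtc, file.path(config$outDir,
                                 paste0("communities_matched_", mt,
                                        ".tsv")))
        for (side in c(1L, 2L)) {
            key <- paste(mt, config$strata[side], sep = "_")
            part <- partitions[[key]]
            col <- c("community_a", "community_b")[side]
            sizeOK <- !is.na(mtc[[col]])
            shared <- setNames(mtc$shared_id[sizeOK],
                               vapply(mtc[[col]][sizeOK], function(ci)
                                   as.character(unique(part@membership[
                                       part@communities[[ci]]])),
                                   character(1L)))
            exportNetwork(networks[[key]], part, roles[[key]],
                          file.path(config$outDir,
                                    paste0("network_", key, ".graphml")),
                          matched = shared)
        }
    }

    # ---- stage: ICC ----
    icc <- NULL
    if (isTRUE(config$icc)) {
        icc <- iccTable(meals, strata,
                        prevalenceThreshold = config$prevalenceThreshold)
        .writeTSV(icc, file.path(config$outDir, "icc_table.tsv"))
    }

    # ---- stage: cross-stratum comparison ----
    comparison <- NULL
    if (isTRUE(config$comparison)) {
        comparison <- do.call(rbind, lapply(config$mealTypes, function(mt) {
            xa <- subsetMeals(meals, mealType = mt,
                              participants = strata[[config$strata[1L]]])
            xb <- subsetMeals(meals, mealType = mt,
                              participants = strata[[config$strata[2L]]])
            cbind(data.frame(meal_type = mt, stringsAsFactors = FALSE),
                  prevalenceComparison(xa, xb, labels = config$strata))
        }))
        .writeTSV(comparison,
                  file.path(config$outDir, "prevalence_comparison.tsv"))
    }

    manifest$n_networks <- length(networks)
    json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null")
    writeLines(json, file.path(config$outDir, "manifest.json"))

    invisible(list(meals = meals, scores = scores, networks = networks,
                   partitions = partitions, roles = roles,
                   matching = matching, trimester = trimester, icc = icc,
                   comparison = comparison, manifest = manifest))
}
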