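#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor qnorm pnorm sd var quantile setNames rnorm runif
#'   rpois rbinom pchisq chisq.test optim
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' MealExperiment: meal-level food-group intake
#'
#' A container for meal-level gram intakes, extending
#' \linkS4class{SummarizedExperiment}. Rows are food groups, columns are
#' eating occasions (meals). The \code{"grams"} assay holds grams of each
#' food group consumed at each meal; \code{colData} carries the meal keys
#' \code{participant_id}, \code{recall_id}, \code{trimester},
#' \code{meal_type} and \code{occasion_index}.
#'
#' Every eating occasion is one column: multiple snacks within a recall are
#' separate columns, and occasions labelled \emph{supper} are merged into
#' \code{meal_type == "dinner"} upstream by \code{\link{normalizeMealType}}.
#'
#' @seealso \code{\link{buildMealMatrix}}, \code{\link{prevalenceFilter}}
#' @aliases MealExperiment-class
#' @exportClass MealExperiment
setClass("MealExperiment", contains = "SummarizedExperiment")

.validMealExperiment <- function(object) {
    msg <- character()
    if (!"grams" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'grams' is required")
    else if (any(SummarizedExperiment::assay(object, "grams") < 0,
                 na.rm = TRUE))
        msg <- c(msg, "gram intakes must be non-negative")
    need <- c("participant_id", "recall_id", "trimester", "meal_type",
              "occasion_index")
    missing <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(missing))
        msg <- c(msg, paste0("colData is missing: ",
                             paste(missing, collapse = ", ")))
    if (!length(msg)) {
        mt <- SummarizedExperiment::colData(object)$meal_type
        if (!all(mt %in% c("breakfast", "lunch", "dinner", "snack")))
            msg <- c(msg, "meal_type must be breakfast/lunch/dinner/snack")
        tri <- SummarizedExperiment::colData(object)$trimester
        if (!all(tri %in% 1:3))
            msg <- c(msg, "trimester must be in 1..3")
    }
    if (length(msg)) msg else TRUE
}
setValidity("MealExperiment", .validMealExperiment)

#' FoodNetwork: a fitted sparse partial-correlation network
#'
#' Result of fitting the rank-based Gaussian copula graphical model to one
#' meal-type-by-stratum meal matrix: the regularized precision matrix, the
#' partial-correlation matrix derived from it, the selected penalty, and
#' per-node consumption prevalence.
#'
#' @slot groups character, retained food groups (after the prevalence
#'   filter) in matrix order.
#' @slot precision regularized precision (inverse covariance) estimate.
#' @slot pcor partial correlations, \eqn{-\Theta_{ij}/\sqrt{\Theta_{ii}
#'   \Theta_{jj}}}, unit diagonal.
#' @slot lambda selected L1 penalty.
#' @slot method rank-correlation method used ("spearman" or "kendall").
#' @slot nMeals number of meals the fit used.
#' @slot prevalence named numeric, proportion of meals in which each
#'   retained group was consumed.
#' @slot excluded character, groups removed by the prevalence filter.
#' @slot cv list with the cross-validation trace (grid, mean held-out
#'   log-likelihood, fold seed), or empty when lambda was supplied.
#' @slot mealType,stratum labels carried through for reporting.
#' @aliases FoodNetwork-class
#' @exportClass FoodNetwork
setClass("FoodNetwork",
    representation(groups = "character", precision = "matrix",
                   pcor = "matrix", lambda = "numeric", method = "character",
                   nMeals = "integer", prevalence = "numeric",
                   excluded = "character", cv = "list",
                   mealType = "character", stratum = "character"))

.validFoodNetwork <- function(object) {
    msg <- character()
    p <- length(object@groups)
    if (!all(dim(object@precision) == p) || !all(dim(object@pcor) == p))
        msg <- c(msg, "precision/pcor dimensions must match groups")
    if (p && max(abs(object@precision - t(object@precision))) > 1e-8)
        msg <- c(msg, "precision must be symmetric")
    if (p && any(diag(object@pcor) != 1))
        msg <- c(msg, "pcor diagonal must be 1")
    if (p && any(abs(object@pcor[upper.tri(object@pcor)]) >= 1))
        msg <- c(msg, "off-diagonal partial correlations must be in (-1,1)")
    if (length(object@lambda) != 1L || object@lambda < 0)
        msg <- c(msg, "lambda must be a single non-negative number")
    if (length(msg)) msg else TRUE
}
setValidity("FoodNetwork", .validFoodNetwork)

setMethod("show", "FoodNetwork", function(object) {
    ne <- nrow(edgeTable(object))
    cat("FoodNetwork (", object@mealType,
        if (nzchar(object@stratum)) paste0(" / ", object@stratum), ")\n",
        sep = "")
    cat("  ", length(object@groups), " food groups (",
        length(object@excluded), " excluded at <5% prevalence), ",
        object@nMeals, " meals\n", sep = "")
    cat("  lambda = ", signif(object@lambda, 4), ", ", ne, " edges, method = ",
        object@method, "\n", sep = "")
})

#' NetworkPartition: Louvain communities of a food network
#'
#' Community structure obtained by modularity maximization on the absolute
#' partial correlations. Communities with at least two food groups are the
#' reported communities; singleton nodes are listed separately as
#' conditionally independent / unassigned.
#'
#' @slot membership named integer, community id per node.
#' @slot modularity weighted Newman-Girvan modularity of the partition.
#' @slot communities list of character vectors (size >= 2 communities).
#' @slot unassigned character, singleton nodes.
#' @slot matched named integer, cross-stratum shared community numbering
#'   (empty until \code{\link{matchCommunities}} is applied).
#' @aliases NetworkPartition-class
#' @exportClass NetworkPartition
setClass("NetworkPartition",
    representation(membership = "integer", modularity = "numeric",
                   communities = "list", unassigned = "character",
                   matched = "integer"))

.validNetworkPartition <- function(object) {
    msg <- character()
    if (is.null(names(object@membership)) && length(object@membership))
        msg <- c(msg, "membership must be named by node")
    if (length(object@modularity) != 1L ||
        object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9)
        msg <- c(msg, "modularity must lie in [-0.5, 1]")
    if (length(msg)) msg else TRUE
}
setValidity("NetworkPartition", .validNetworkPartition)

setMethod("show", "NetworkPartition", function(object) {
    cat("NetworkPartition: ", length(object@communities),
        " communities (>=2 nodes), ", length(object@unassigned),
        " conditionally independent nodes, Q = ",
        round(object@modularity, 4), "\n", sep = "")
})

# ---- accessors ----

#' Accessors for fitted food networks and partitions
#'
#' @param object a \linkS4class{FoodNetwork} or
#'   \linkS4class{NetworkPartition}.
#' @return \code{foodGroups}: retained group names. \code{partialCors}:
#'   the partial-correlation matrix. \code{selectedLambda}: the penalty
#'   used. \code{nodePrevalence}: per-group proportion of meals with
#'   positive intake. \code{edgeTable}: data.frame of edges
#'   (\code{group_i}, \code{group_j}, \code{partial_correlation},
#'   \code{weight}, \code{sign}). \code{communityMembership}: named
#'   integer community ids.
#' @name network-accessors
#' @examples
#' pm <- generateSparsePrecision(4, 0.3, seed = 1)
#' X <- exp(matrix(rnorm(400), 100) %*% chol(pm$Sigma))
#' colnames(X) <- c("milk", "cereal", "fruit", "bread")
#' net <- fitMealNetwork(
#'     prevalenceFilter(buildMealMatrix(
#'         data.frame(participant_id = rep(paste0("P", 1:100), 4),
#'                    recall_id = rep(paste0("P", 1:100), 4),
#'                    trimester = 1L, occasion_index = 1L,
#'                    occasion_label = "breakfast",
#'                    food_code = rep(colnames(X), each = 100),
#'                    amount_g = as.vector(X),
#'                    energy_kcal = as.vector(X)),
#'         makeTaxonomy(setNames(colnames(X), colnames(X))))),
#'     mealType = "breakfast", lambda = 0.1)
#' edgeTable(net)
NULL

#' @rdname network-accessors
#' @export
foodGroups <- function(object) object@groups

#' @rdname network-accessors
#' @export
partialCors <- function(object) object@pcor

#' @rdname network-accessors
#' @export
selectedLambda <- function(object) object@lambda

#' @rdname network-accessors
#' @export
nodePrevalence <- function(object) {
    if (is(object, "MealExperiment"))
        rowMeans(SummarizedExperiment::assay(object, "grams") > 0)
    else object@prevalence
}

#' @rdname network-accessors
#' @export
communityMembership <- function(object) object@membership

#' @rdname network-accessors
#' @export
edgeTable <- function(object) {
    stopifnot(is(object, "FoodNetwork"))
    p <- length(object@groups)
    out <- data.frame(group_i = character(), group_j = character(),
                      partial_correlation = numeric(), weight = numeric(),
                      sign = character(), stringsAsFactors = FALSE)
    if (p < 2L) return(out)
    idx <- which(upper.tri(object@pcor) & abs(object@pcor) > 1e-8,
                 arr.ind = TRUE)
    if (!nrow(idx)) return(out)
    pc <- object@pcor[idx]
    data.frame(group_i = object@groups[idx[, 1L]],
               group_j = object@groups[idx[, 2L]],
               partial_correlation = pc, weight = abs(pc),
               sign = ifelse(pc >= 0, "positive", "negative"),
               stringsAsFactors = FALSE)
}

# internal constructor shared by the fitters
.networkFromPrecision <- function(Theta, prevalence, lambda, nMeals,
                                  method = "spearman", excluded = character(),
                                  cv = list(), mealType = "", stratum = "") {
    groups <- names(prevalence)
    if (is.null(groups)) groups <- rownames(Theta)
    d <- sqrt(diag(Theta))
    P <- -Theta / tcrossprod(d)
    diag(P) <- 1
    P[abs(P) < 1e-8] <- 0        # epsilon floor guards float noise
    P <- (P + t(P)) / 2
    diag(P) <- 1
    dimnames(Theta) <- dimnames(P) <- list(groups, groups)
    new("FoodNetwork", groups = groups, precision = Theta, pcor = P,
        lambda = lambda, method = method, nMeals = as.integer(nMeals),
        prevalence = prevalence, excluded = excluded, cv = cv,
        mealType = mealType, stratum = stratum)
}
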