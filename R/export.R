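#' Export a food network as GraphML plus TSV side tables
#'
#' Writes a GraphML file (loadable by standard graph viewers, including
#' Cytoscape) with node attributes \code{label}, \code{prevalence_pct},
#' \code{community}, \code{matched_community} and \code{role}, and edge
#' attributes \code{weight} (absolute partial correlation), \code{sign}
#' and \code{partial_correlation}; and TSV node/edge tables alongside.
#'
#' @param model a \linkS4class{FoodNetwork}.
#' @param partition optional \linkS4class{NetworkPartition}.
#' @param roles optional data.frame from \code{\link{nodeRoles}}.
#' @param path output GraphML path; side tables get \code{_nodes.tsv} /
#'   \code{_edges.tsv} suffixes.
#' @param matched optional named integer of shared community numbers per
#'   community id (from \code{\link{matchCommunities}}).
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(model, partition = NULL, roles = NULL, path,
                          matched = NULL) {
    g <- buildGraph(model)
    igraph::V(g)$label <- igraph::V(g)$name
    if (!is.null(partition)) {
        memb <- partition@membership[igraph::V(g)$name]
        igraph::V(g)$community <- as.integer(memb)
        if (!is.null(matched)) {
            mm <- matched[as.character(memb)]
            igraph::V(g)$matched_community <-
                ifelse(is.na(mm), -1L, as.integer(mm))
        }
    }
    if (!is.null(roles))
        igraph::V(g)$role <- roles$role[match(igraph::V(g)$name,
                                              roles$node)]
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    igraph::write_graph(g, path, format = "graphml")
    base <- sub("\\.graphml$", "", path)
    nt <- data.frame(node = igraph::V(g)$name,
                     prevalence_pct = igraph::V(g)$prevalence_pct,
                     stringsAsFactors = FALSE)
    if (!is.null(partition)) nt$community <- igraph::V(g)$community
    if (!is.null(roles)) {
        nt$wc <- roles$wc[match(nt$node, roles$node)]
        nt$pc <- roles$pc[match(nt$node, roles$node)]
        nt$role <- roles$role[match(nt$node, roles$node)]
    }
    .writeTSV(nt, paste0(base, "_nodes.tsv"))
    .writeTSV(edgeTable(model), paste0(base, "_edges.tsv"))
    invisible(c(graphml = path, nodes = paste0(base, "_nodes.tsv"),
                edges = paste0(base, "_edges.tsv")))
}
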