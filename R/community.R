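#' Weighted graph from a fitted food network
#'
#' One undirected edge per nonzero off-diagonal partial correlation,
#' weighted by its absolute value (community detection operates on
#' \eqn{|p_{ij}|}); the sign and the signed partial correlation are kept
#' as edge attributes. Node attributes carry consumption prevalence.
#'
#' @param model a \linkS4class{FoodNetwork}.
#' @return an \pkg{igraph} undirected graph.
#' @export
buildGraph <- function(model) {
    et <- edgeTable(model)
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(model@groups),
                              name = model@groups,
                              prevalence_pct = 100 * unname(model@prevalence))
    if (nrow(et))
        g <- igraph::add_edges(
            g, rbind(match(et$group_i, model@groups),
                     match(et$group_j, model@groups)),
            weight = et$weight, sign = et$sign,
            partial_correlation = et$partial_correlation)
    g
}

#' Weighted Newman-Girvan modularity
#'
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(w_{ij} - \frac{k_i k_j}{2m}\right)
#' \delta(c_i, c_j)} with \eqn{k} the weighted degree and \eqn{m} the
#' total edge weight. Defined as 0 for an empty graph. This is an
#' independent implementation of the quantity the Louvain algorithm
#' maximizes and is used to cross-check returned partitions.
#'
#' @param graph igraph graph with a \code{weight} edge attribute (weights
#'   default to 1 if absent).
#' @param membership named or ordered community ids per node.
#' @return modularity Q in [-0.5, 1].
#' @export
modularityQ <- function(graph, membership) {
    nv <- igraph::vcount(graph)
    if (!is.null(names(membership)) && !is.null(igraph::V(graph)$name))
        membership <- membership[igraph::V(graph)$name]
    stopifnot(length(membership) == nv)
    el <- igraph::as_edgelist(graph, names = FALSE)
    if (!nrow(el)) return(0)
    w <- igraph::E(graph)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    m <- sum(w)
    k <- numeric(nv)
    for (e in seq_len(nrow(el))) {
        k[el[e, 1L]] <- k[el[e, 1L]] + w[e]
        k[el[e, 2L]] <- k[el[e, 2L]] + w[e]
    }
    same <- membership[el[, 1L]] == membership[el[, 2L]]
    qEdges <- sum(w[same]) / m
    qNull <- sum(vapply(split(k, membership), function(ki)
        (sum(ki) / (2 * m))^2, numeric(1L)))
    qEdges - qNull
}

#' Louvain community detection on absolute partial correlations
#'
#' Runs the Louvain method (greedy modularity maximization with local
#' moves and graph aggregation, resolution 1) on the edge weights
#' \eqn{|p_{ij}|}. The node sweep order inside the algorithm is
#' randomized, so a seed fixes the result. Communities with at least two
#' food groups are the reported communities; singletons are reported
#' separately as conditionally independent / unassigned nodes.
#'
#' @param graph igraph graph from \code{\link{buildGraph}}.
#' @param seed RNG seed (default 1).
#' @return a \linkS4class{NetworkPartition}.
#' @export
louvainPartition <- function(graph, seed = 1L) {
    nv <- igraph::vcount(graph)
    nodes <- igraph::V(graph)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(nv))
    if (igraph::ecount(graph) == 0L) {
        memb <- setNames(seq_len(nv), nodes)
        return(new("NetworkPartition", membership = memb, modularity = 0,
                   communities = list(), unassigned = nodes,
                   matched = integer()))
    }
    set.seed(seed)
    cl <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight)
    memb <- setNames(as.integer(igraph::membership(cl)), nodes)
    q <- modularityQ(graph, memb)
    sizes <- table(memb)
    big <- as.integer(names(sizes)[sizes >= 2L])
    comms <- lapply(big, function(cid) nodes[memb == cid])
    new("NetworkPartition", membership = memb, modularity = q,
        communities = comms,
        unassigned = nodes[memb %in%
            as.integer(names(sizes)[sizes < 2L])],
        matched = integer())
}

# internal: binary (or weighted) adjacency and per-node community counts
.communityCounts <- function(graph, membership, weighted = FALSE) {
    nv <- igraph::vcount(graph)
    nodes <- igraph::V(graph)$name
    if (!is.null(names(membership))) membership <- membership[nodes]
    el <- igraph::as_edgelist(graph, names = FALSE)
    w <- if (weighted) igraph::E(graph)$weight else rep(1, nrow(el))
    comms <- sort(unique(membership))
    K <- matrix(0, nv, length(comms),
                dimnames = list(nodes, as.character(comms)))
    for (e in seq_len(nrow(el))) {
        i <- el[e, 1L]; j <- el[e, 2L]
        K[i, as.character(membership[j])] <-
            K[i, as.character(membership[j])] + w[e]
        K[j, as.character(membership[i])] <-
            K[j, as.character(membership[i])] + w[e]
    }
    K
}

#' Within-community degree z-score (WC)
#'
#' How strongly a node connects inside its own community:
#' \eqn{WC_i = (\kappa_i - \bar\kappa_{c_i}) / \sigma_{\kappa_{c_i}}}
#' where \eqn{\kappa_i} counts node i's edges to its own community and
#' mean/sd are taken over that community (population sd). A community with
#' constant internal degree (sd 0), and any singleton, gets WC = 0 by
#' convention. Binary edge counts by default, matching the original
#' cartography method; \code{weighted = TRUE} uses edge weights.
#'
#' @param graph igraph graph.
#' @param membership community ids (named by node).
#' @param weighted use edge weights instead of counts.
#' @return named numeric vector of WC z-scores.
#' @export
withinCommunityDegree <- function(graph, membership, weighted = FALSE) {
    K <- .communityCounts(graph, membership, weighted)
    nodes <- rownames(K)
    memb <- if (!is.null(names(membership))) membership[nodes] else membership
    kappa <- K[cbind(seq_along(nodes), match(as.character(memb),
                                             colnames(K)))]
    wc <- setNames(numeric(length(nodes)), nodes)
    for (cid in unique(memb)) {
        sel <- memb == cid
        mu <- mean(kappa[sel])
        sdev <- sqrt(mean((kappa[sel] - mu)^2))   # population sd
        wc[sel] <- if (sdev > 0) (kappa[sel] - mu) / sdev else 0
    }
    wc
}

#' Participation coefficient (PC)
#'
#' How evenly a node's edges spread over communities:
#' \eqn{PC_i = 1 - \sum_s (\kappa_{is} / k_i)^2}; 0 when all edges stay in
#' the node's own community, approaching 1 when edges are uniformly
#' distributed among communities. Isolated nodes (degree 0) get PC = 0.
#'
#' @inheritParams withinCommunityDegree
#' @return named numeric vector of PCs in [0, 1].
#' @export
participationCoefficient <- function(graph, membership, weighted = FALSE) {
    K <- .communityCounts(graph, membership, weighted)
    k <- rowSums(K)
    pc <- 1 - rowSums((K / pmax(k, 1))^2)
    pc[k == 0] <- 0
    setNames(pc, rownames(K))
}

#' Classify node roles from (WC, PC)
#'
#' Hubs are nodes with WC >= 1.0 (threshold adapted to sparse food
#' networks). Hubs split by PC into provincial (<= 0.30), connector
#' (> 0.30 and <= 0.75) and kinless (> 0.75). Non-hubs split into
#' ultra-peripheral (<= 0.05), peripheral (> 0.05 and <= 0.62), non-hub
#' connector (> 0.62 and <= 0.80) and non-hub kinless (>= 0.80); the two
#' non-hub bands overlap at exactly PC = 0.80, resolved here as kinless
#' (the kinless rule wins). Nodes with no edges are \code{isolated}.
#'
#' @param wc,pc numeric vectors (recycled to common length).
#' @param isolated logical vector marking degree-0 nodes.
#' @return character vector of roles.
#' @export
classifyRole <- function(wc, pc, isolated = FALSE) {
    n <- max(length(wc), length(pc), length(isolated))
    wc <- rep_len(wc, n); pc <- rep_len(pc, n)
    isolated <- rep_len(isolated, n)
    out <- character(n)
    for (i in seq_len(n)) {
        out[i] <- if (isolated[i]) "isolated"
        else if (wc[i] >= 1.0) {
            if (pc[i] <= 0.30) "provincial_hub"
            else if (pc[i] <= 0.75) "connector_hub"
            else "kinless_hub"
        } else {
            if (pc[i] >= 0.80) "non_hub_kinless"   # 0.80 tie -> kinless
            else if (pc[i] > 0.62) "non_hub_connector"
            else if (pc[i] > 0.05) "peripheral"
            else "ultra_peripheral"
        }
    }
    out
}

#' Node-role table for a partitioned network
#'
#' Computes WC, PC and the role label for every node. Singleton
#' (conditionally independent) nodes are excluded from the community WC
#' statistics by construction (their community is themselves, WC = 0) and
#' are labelled \code{isolated} when they have no edges at all.
#'
#' @param graph igraph graph from \code{\link{buildGraph}}.
#' @param partition a \linkS4class{NetworkPartition}.
#' @param weighted use weighted degrees (default binary counts).
#' @return data.frame: \code{node}, \code{community}, \code{wc},
#'   \code{pc}, \code{role}.
#' @export
nodeRoles <- function(graph, partition, weighted = FALSE) {
    memb <- partition@membership
    wc <- withinCommunityDegree(graph, memb, weighted)
    pc <- participationCoefficient(graph, memb, weighted)
    deg <- igraph::degree(graph)
    nodes <- names(wc)
    data.frame(node = nodes, community = unname(memb[nodes]),
               wc = unname(wc), pc = unname(pc),
               role = classifyRole(unname(wc), unname(pc),
                                   unname(deg[nodes]) == 0),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Match communities across strata by node overlap
#'
#' Communities composed of similar food combinations in two strata are
#' given the same number: pairs of communities are greedily matched in
#' decreasing Jaccard order (ties broken by community ids, making the
#' pairing symmetric in its arguments); pairs below the Jaccard threshold
#' stay unmatched and receive fresh numbers.
#'
#' @param partitionA,partitionB \linkS4class{NetworkPartition}s (their
#'   reported size->=2 communities are matched).
#' @param threshold minimum Jaccard index for a match (default 0.25).
#' @return data.frame: \code{shared_id}, \code{community_a},
#'   \code{community_b} (NA when unmatched), \code{jaccard}.
#' @export
matchCommunities <- function(partitionA, partitionB, threshold = 0.25) {
    ca <- partitionA@communities
    cb <- partitionB@communities
    pairs <- expand.grid(a = seq_along(ca), b = seq_along(cb))
    if (nrow(pairs)) {
        pairs$jaccard <- mapply(function(a, b) {
            length(intersect(ca[[a]], cb[[b]])) /
                length(union(ca[[a]], cb[[b]]))
        }, pairs$a, pairs$b)
        pairs <- pairs[order(-pairs$jaccard, pairs$a, pairs$b), ,
                       drop = FALSE]
    }
    usedA <- logical(length(ca)); usedB <- logical(length(cb))
    rows <- list(); nextId <- 1L
    for (r in seq_len(nrow(pairs))) {
        a <- pairs$a[r]; b <- pairs$b[r]
        if (pairs$jaccard[r] < threshold) break
        if (usedA[a] || usedB[b]) next
        usedA[a] <- usedB[b] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
            shared_id = nextId, community_a = a, community_b = b,
            jaccard = pairs$jaccard[r])
        nextId <- nextId + 1L
    }
    for (a in which(!usedA)) {
        rows[[length(rows) + 1L]] <- data.frame(
            shared_id = nextId, community_a = a, community_b = NA_integer_,
            jaccard = NA_real_)
        nextId <- nextId + 1L
    }
    for (b in which(!usedB)) {
        rows[[length(rows) + 1L]] <- data.frame(
            shared_id = nextId, community_a = NA_integer_, community_b = b,
            jaccard = NA_real_)
        nextId <- nextId + 1L
    }
    if (!length(rows))
        return(data.frame(shared_id = integer(), community_a = integer(),
                          community_b = integer(), jaccard = numeric()))
    do.call(rbind, rows)
}
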