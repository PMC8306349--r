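twoTriangles <- function() {
    g <- igraph::make_graph(edges = c(1, 2, 2, 3, 1, 3, 4, 5, 5, 6, 4, 6),
                            directed = FALSE)
    igraph::V(g)$name <- letters[1:6]
    igraph::E(g)$weight <- 1
    g
}

smallNetwork <- function() {
    # 5-group network with 3 edges, one negative
    Theta <- diag(5L)
    Theta[1, 2] <- Theta[2, 1] <- -0.3     # pcor +0.3
    Theta[2, 3] <- Theta[3, 2] <- 0.4      # pcor -0.4
    Theta[4, 5] <- Theta[5, 4] <- -0.2     # pcor +0.2
    prev <- setNames(seq(0.2, 0.6, length.out = 5L),
                     c("milk", "cereal", "fruit", "bread", "cheese"))
    mealnets:::.networkFromPrecision(Theta, prev, lambda = 0.1,
                                     nMeals = 100L)
}

test_that("graphs carry absolute weights with signs preserved", {
    net <- smallNetwork()
    g <- buildGraph(net)
    expect_equal(igraph::ecount(g), 3L)
    expect_equal(igraph::vcount(g), 5L)
    et <- edgeTable(net)
    neg <- et[et$group_i == "cereal" & et$group_j == "fruit", ]
    expect_equal(neg$sign, "negative")
    expect_equal(neg$weight, 0.4)
    expect_equal(neg$partial_correlation, -0.4)
    # edgeless model
    empty <- mealnets:::.networkFromPrecision(diag(3L),
        setNames(rep(0.5, 3L), c("a", "b", "c")), 0.1, 50L)
    expect_equal(igraph::ecount(buildGraph(empty)), 0L)
})

test_that("modularity matches hand computations and igraph", {
    g <- twoTriangles()
    all_one <- setNames(rep(1L, 6L), letters[1:6])
    expect_equal(modularityQ(g, all_one), 0)
    triangles <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])
    expect_equal(modularityQ(g, triangles), 0.5)   # hand: 1 - 2*(1/2)^2
    singletons <- setNames(1:6, letters[1:6])
    expect_lt(modularityQ(g, singletons), 0)
    # against igraph on a weighted random graph
    set.seed(5)
    gr <- igraph::sample_gnp(12L, 0.3)
    igraph::E(gr)$weight <- runif(igraph::ecount(gr), 0.1, 1)
    memb <- sample(1:3, 12L, replace = TRUE)
    expect_equal(modularityQ(gr, memb),
                 igraph::modularity(gr, memb,
                                    weights = igraph::E(gr)$weight))
    expect_equal(modularityQ(igraph::make_empty_graph(3, directed = FALSE),
                             1:3), 0)
})

test_that("louvain recovers planted disjoint triangles exactly", {
    g <- twoTriangles()
    part <- louvainPartition(g, seed = 1L)
    memb <- communityMembership(part)
    expect_length(unique(memb), 2L)
    expect_length(unique(memb[c("a", "b", "c")]), 1L)
    expect_length(unique(memb[c("d", "e", "f")]), 1L)
    expect_equal(part@modularity, 0.5)
    # returned Q is self-consistent with the independent recomputation
    expect_equal(part@modularity, modularityQ(g, memb))
    # never worse than leaving every node alone
    expect_gte(part@modularity, modularityQ(g, setNames(1:6,
                                                        letters[1:6])))
    expect_length(part@communities, 2L)
    expect_length(part@unassigned, 0L)
})

test_that("edgeless graphs yield all-unassigned singleton partitions", {
    net <- mealnets:::.networkFromPrecision(diag(4L),
        setNames(rep(0.3, 4L), c("a", "b", "c", "d")), 0.2, 40L)
    part <- louvainPartition(buildGraph(net), seed = 1L)
    expect_equal(part@modularity, 0)
    expect_setequal(part@unassigned, c("a", "b", "c", "d"))
    expect_length(part@communities, 0L)
})

test_that("WC and PC match brute-force counts on a hand-built graph", {
    fx <- cartographyFixture()
    wc <- withinCommunityDegree(fx$graph, fx$membership)
    pc <- participationCoefficient(fx$graph, fx$membership)

    # community 1 internal degrees: a,b,c,d all 3 -> sd 0 -> WC 0
    expect_equal(unname(wc[c("a", "b", "c", "d")]), rep(0, 4L))
    # community 2 internal degrees: e=3, f=2, g=3, h=2; mean 2.5, sd 0.5
    expect_equal(unname(wc["e"]), 1)
    expect_equal(unname(wc["f"]), -1)
    expect_equal(unname(wc["g"]), 1)
    # star-community hand case: hub 3 leaves
    star <- igraph::make_star(4L, mode = "undirected")
    igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
    igraph::E(star)$weight <- 1
    wcs <- withinCommunityDegree(star, setNames(rep(1L, 4L),
                                                c("hub", "l1", "l2", "l3")))
    expect_equal(unname(wcs["hub"]), (3 - 1.5) / sqrt(0.75))  # 1.732...

    # PC: a has 3 internal + 1 external of 4 edges -> 1-(9+1)/16
    expect_equal(unname(pc["a"]), 1 - (3 / 4)^2 - (1 / 4)^2)
    expect_equal(unname(pc["b"]), 0)               # all internal
    expect_equal(unname(pc["e"]), 1 - (3 / 4)^2 - (1 / 4)^2)
    expect_equal(unname(pc["i"]), 0)
    # two edges split across two communities -> 0.5
    gg <- igraph::make_graph(c("x", "y", "x", "z"), directed = FALSE)
    igraph::E(gg)$weight <- 1
    pcx <- participationCoefficient(gg, c(x = 1L, y = 1L, z = 2L))
    expect_equal(unname(pcx["x"]), 0.5)
    # WC averages to zero inside each community with spread
    expect_equal(mean(wc[c("e", "f", "g", "h")]), 0, tolerance = 1e-12)
})

test_that("PC is bounded by 1 - 1/S and grows as edges spread", {
    # enumerate a node of degree 6 spread over S communities
    for (S in 1:6) {
        spread <- rep(floor(6 / S), S)
        spread[seq_len(6 - sum(spread))] <- spread[seq_len(6 - sum(spread))] + 1
        pc <- 1 - sum((spread / 6)^2)
        expect_lte(pc, 1 - 1 / S + 1e-12)
        if (S > 1L) {
            lumped <- c(7 - S, rep(1, S - 1L))   # less even split
            expect_gte(pc, 1 - sum((lumped / 6)^2) - 1e-12)
        }
    }
})

test_that("role classification follows the cartography rule table", {
    expect_equal(classifyRole(1.2, 0.2), "provincial_hub")
    expect_equal(classifyRole(1.2, 0.8), "kinless_hub")
    expect_equal(classifyRole(0.5, 0.03), "ultra_peripheral")
    expect_equal(classifyRole(1.0, 0.30), "provincial_hub")  # inclusive
    eps <- 1e-9
    grid <- expand.grid(wc = c(0.99, 1.0, 1.01),
                        pc = c(0.05 - eps, 0.05, 0.05 + eps,
                               0.30, 0.30 + eps, 0.62, 0.62 + eps,
                               0.75, 0.75 + eps, 0.80 - eps, 0.80,
                               0.80 + eps))
    roles <- classifyRole(grid$wc, grid$pc)
    hub <- grid$wc >= 1.0
    expect_true(all(roles[hub & grid$pc <= 0.30] == "provincial_hub"))
    expect_true(all(roles[hub & grid$pc > 0.30 & grid$pc <= 0.75] ==
                    "connector_hub"))
    expect_true(all(roles[hub & grid$pc > 0.75] == "kinless_hub"))
    expect_true(all(roles[!hub & grid$pc <= 0.05] == "ultra_peripheral"))
    expect_true(all(roles[!hub & grid$pc > 0.05 & grid$pc <= 0.62] ==
                    "peripheral"))
    expect_true(all(roles[!hub & grid$pc > 0.62 & grid$pc < 0.80] ==
                    "non_hub_connector"))
    # overlap at exactly 0.80 resolves to kinless
    expect_true(all(roles[!hub & grid$pc >= 0.80] == "non_hub_kinless"))
    # totality over a dense sweep: exactly one role everywhere
    sweep <- expand.grid(wc = seq(-2, 2, by = 0.1),
                         pc = seq(0, 1, by = 0.01))
    expect_true(all(classifyRole(sweep$wc, sweep$pc) %in%
        c("provincial_hub", "connector_hub", "kinless_hub",
          "ultra_peripheral", "peripheral", "non_hub_connector",
          "non_hub_kinless")))
})

test_that("node role table combines WC, PC, and isolation", {
    fx <- cartographyFixture()
    part <- new("NetworkPartition", membership = fx$membership,
                modularity = modularityQ(fx$graph, fx$membership),
                communities = list(c("a", "b", "c", "d"),
                                   c("e", "f", "g", "h"), c("i", "j")),
                unassigned = character(), matched = integer())
    rt <- nodeRoles(fx$graph, part)
    expect_setequal(rt$node, letters[1:10])
    expect_equal(rt$role[rt$node == "e"], "connector_hub")   # WC 1, PC 0.375
    expect_equal(rt$role[rt$node == "a"], "peripheral")      # WC 0, PC 0.375
    expect_true(all(rt$role[rt$node %in% c("b", "c", "d")] ==
                    "ultra_peripheral"))
})

test_that("community matching is greedy on Jaccard and stable to swapping", {
    mkpart <- function(comms, allNodes) {
        memb <- integer(0)
        for (i in seq_along(comms))
            memb[comms[[i]]] <- i
        new("NetworkPartition",
            membership = setNames(memb[allNodes], allNodes),
            modularity = 0, communities = comms,
            unassigned = setdiff(allNodes, unlist(comms)),
            matched = integer())
    }
    nodes <- letters[1:8]
    pa <- mkpart(list(c("a", "b", "c"), c("d", "e", "f")), nodes)
    m <- matchCommunities(pa, pa)
    expect_equal(m$jaccard, c(1, 1))
    expect_equal(m$community_a, m$community_b)

    pb <- mkpart(list(c("g", "h")), nodes)
    m2 <- matchCommunities(pa, pb)
    expect_true(all(is.na(m2$jaccard)))
    expect_equal(length(unique(m2$shared_id)), nrow(m2))

    # one community split in two: larger overlap inherits the number
    pc_ <- mkpart(list(c("a", "b"), c("c")), nodes)
    m3 <- matchCommunities(pa, pc_)
    matched <- m3[!is.na(m3$community_b) & !is.na(m3$community_a), ]
    expect_equal(matched$community_a, 1L)
    expect_equal(matched$community_b, 1L)   # {a,b}: J=2/3 beats {c}: 1/3

    # swapped arguments give the same pairing
    m4 <- matchCommunities(pc_, pa)
    pair34 <- matched[, c("community_a", "community_b")]
    pair43 <- m4[!is.na(m4$community_a) & !is.na(m4$community_b),
                 c("community_b", "community_a")]
    expect_equal(unname(unlist(pair34)), unname(unlist(pair43)))
})
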