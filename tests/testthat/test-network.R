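test_that("network construction counts nodes, edges and weights per stratum", {
  net <- build_network(events_frame(c("S", "S"), c("T", "T")))
  expect_identical(net$n, 2L)
  expect_identical(net$m, 1L)
  expect_identical(net$edges$weight, 2L)
  net2 <- build_network(events_frame(c("S", "T"), c("T", "S")))
  expect_identical(net2$n, 2L)
  expect_identical(net2$m, 2L)
  empty <- build_network(events_frame(character(), character()))
  expect_identical(empty$n, 0L)
  expect_identical(empty$m, 0L)
  mixed <- rbind(events_frame("A", "B", fy = 2016L),
                 events_frame("A", "B", fy = 2017L))
  expect_error(build_network(mixed), class = "shareduse_stratum_error")
})

test_that("density matches its closed form on toy graphs", {
  net <- build_network(events_frame(c("A", "B", "A", "C"),
                                    c("B", "A", "C", "D")))
  expect_equal(network_density(net), 4 / 12)
  complete3 <- expand.grid(s = c("A", "B", "C"), t = c("A", "B", "C"),
                           stringsAsFactors = FALSE)
  complete3 <- complete3[complete3$s != complete3$t, ]
  expect_equal(network_density(build_network(
    events_frame(complete3$s, complete3$t))), 1.0)
  expect_equal(network_density(build_network(events_frame("A", "B"))), 0.5)
  single <- build_network(events_frame(character(), character()))
  expect_warning(d <- network_density(single), "undefined")
  expect_true(is.na(d))
})

test_that("reciprocity follows the dyad census in both conventions", {
  net <- build_network(events_frame(c("A", "B", "A"), c("B", "A", "C")))
  cen <- dyad_census(net)
  expect_identical(cen$mutual, 1L)
  expect_identical(cen$asymmetric, 1L)
  expect_equal(network_reciprocity(net), 0.5)
  expect_equal(network_reciprocity(net, "edgewise"), 2 / 3)
  # tournament: no mutual pairs
  tour <- build_network(events_frame(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(network_reciprocity(tour), 0)
  # fully symmetric
  sym <- build_network(events_frame(c("A", "B", "B", "C"),
                                    c("B", "A", "C", "B")))
  expect_equal(network_reciprocity(sym), 1)
  # weights do not matter
  wt <- build_network(events_frame(c("A", "A", "A", "B"),
                                   c("B", "B", "B", "A")))
  expect_equal(network_reciprocity(wt), 1)
  empty <- build_network(events_frame(character(), character()))
  expect_warning(r <- network_reciprocity(empty), "undefined")
  expect_true(is.na(r))
})

test_that("modularity matches direct evaluation of the Newman-Girvan sum", {
  # independent mini-oracle: evaluate Q from the definition
  direct_Q <- function(net, memb) {
    nodes <- net$nodes
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      A[e$source, e$target] <- A[e$source, e$target] + e$weight
      A[e$target, e$source] <- A[e$target, e$source] + e$weight
    }
    W2 <- sum(A)
    k <- rowSums(A)
    q <- 0
    for (i in nodes) for (j in nodes) {
      if (memb[i] == memb[j]) q <- q + A[i, j] / W2 - k[i] * k[j] / W2^2
    }
    unname(q)
  }
  two_dyads <- build_network(events_frame(c("A", "B", "C", "D"),
                                          c("B", "A", "D", "C")))
  comp <- c(A = 1, B = 1, C = 2, D = 2)
  expect_equal(network_modularity(two_dyads, comp), 0.5)
  expect_equal(direct_Q(two_dyads, comp), 0.5)
  # all nodes in one community: Q = 0
  expect_equal(network_modularity(two_dyads, c(A = 1, B = 1, C = 1, D = 1)), 0)
  # all singletons: Q = -sum (k_i/2W)^2 < 0
  singl <- c(A = 1, B = 2, C = 3, D = 4)
  expect_equal(network_modularity(two_dyads, singl), -0.25)
  expect_equal(direct_Q(two_dyads, singl),
               network_modularity(two_dyads, singl))
  # random weighted graphs vs direct evaluation and igraph
  set.seed(42)
  for (r in 1:10) {
    nodes <- LETTERS[1:6]
    src <- sample(nodes, 10, TRUE); tgt <- sample(nodes, 10, TRUE)
    keep <- src != tgt
    net <- build_network(events_frame(src[keep], tgt[keep]))
    memb <- stats::setNames(sample(1:3, net$n, TRUE), net$nodes)
    expect_equal(network_modularity(net, memb), direct_Q(net, memb))
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$nodes)
    gu <- igraph::as_undirected(g, mode = "collapse",
                                edge.attr.comb = list(weight = "sum"))
    expect_equal(network_modularity(net, memb),
                 igraph::modularity(gu, memb[igraph::V(gu)$name],
                                    weights = igraph::E(gu)$weight))
  }
  expect_error(network_modularity(two_dyads, c(A = 1, B = 1, C = 1)),
               "D", class = "shareduse_partition_error")
})

test_that("Louvain finds known optima, is seeded, and improves monotonically", {
  two_dyads <- build_network(events_frame(c("A", "B", "C", "D"),
                                          c("B", "A", "D", "C")))
  for (s in 0:4) {
    p <- louvain_communities(two_dyads, seed = s)
    expect_equal(p$Q, 0.5)
    expect_identical(length(unique(p$membership)), 2L)
    expect_identical(unname(p$membership["A"]), unname(p$membership["B"]))
    expect_identical(unname(p$membership["C"]), unname(p$membership["D"]))
  }
  # exhaustive search over all 15 partitions of 4 nodes confirms 0.5 optimal
  opt <- best_partition_exhaustive(two_dyads)
  expect_equal(opt$Q, 0.5)
  # single node: one community, Q = 0
  single <- build_network(events_frame("A", "B"))
  single$nodes <- "A"; single$edges <- single$edges[0, ]; single$n <- 1L
  single$m <- 0L
  expect_equal(louvain_communities(single)$Q, 0)
  # same seed -> same partition
  g <- generate_claims(random_generator_config(2L))
  ev <- g$truth$events
  st <- ev[ev$modality == ev$modality[1] &
             ev$fiscal_year == ev$fiscal_year[1], ]
  net <- build_network(st)
  expect_identical(louvain_communities(net, seed = 9)$membership,
                   louvain_communities(net, seed = 9)$membership)
  # Q never decreases across passes (instrumentation hook)
  p <- louvain_communities(net, seed = 1)
  expect_true(all(diff(attr(p, "pass_Q")) >= -1e-12))
})

test_that("Louvain is near-optimal on random small graphs", {
  set.seed(2024)
  for (r in 1:40) {
    n <- sample(4:8, 1)
    nodes <- LETTERS[1:n]
    ne <- sample(3:14, 1)
    src <- sample(nodes, ne, TRUE); tgt <- sample(nodes, ne, TRUE)
    keep <- src != tgt
    if (!any(keep)) next
    net <- build_network(events_frame(src[keep], tgt[keep]))
    lv <- louvain_communities(net, seed = r)
    opt <- best_partition_exhaustive(net)
    expect_gte(opt$Q + 1e-12, lv$Q)        # never exceeds the optimum
    expect_gte(lv$Q, 0.95 * opt$Q - 1e-9)  # and comes within 5%
  }
})

test_that("network export round-trips through GraphML and edge-list TSV", {
  net <- build_network(events_frame(c("A", "B", "A"), c("B", "A", "C")))
  part <- louvain_communities(net, seed = 0)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml", partition = part)
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes)
  expect_equal(igraph::ecount(g), net$m)
  el <- igraph::as_data_frame(g)
  key <- function(df) paste(df[[1]], df[[2]], df[[3]])
  expect_setequal(key(el[, c("from", "to", "weight")]),
                  key(net$edges))
  expect_setequal(igraph::V(g)$community,
                  unname(part$membership[igraph::V(g)$name]))
  # empty network still writes a valid file
  path2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(build_network(events_frame(character(), character())),
                 path2, "graphml")
  g2 <- igraph::read_graph(path2, format = "graphml")
  expect_equal(igraph::ecount(g2), 0)
  # edgelist TSV
  path3 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, path3, "edgelist_tsv")
  tsv <- utils::read.delim(path3)
  expect_identical(names(tsv), c("source", "target", "weight"))
  expect_setequal(key(tsv), key(net$edges))
})

test_that("density rises under edge addition and both metrics stay in [0,1]", {
  set.seed(8)
  nodes <- LETTERS[1:6]
  pool <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pool <- pool[pool$s != pool$t, ]
  pool <- pool[sample(nrow(pool)), ]
  last <- -1
  for (k in seq(2, 20, by = 3)) {
    net <- build_network(events_frame(pool$s[1:k], pool$t[1:k]))
    if (net$n == 6L) {
      d <- network_density(net)
      expect_true(d >= 0 && d <= 1)
      expect_gt(d, last)
      last <- d
      r <- suppressWarnings(network_reciprocity(net))
      expect_true(is.na(r) || (r >= 0 && r <= 1))
    }
  }
})
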