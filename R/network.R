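#' Build a per-stratum directed referral network from events
#'
#' Nodes are the facilities appearing in at least one event of the stratum;
#' the weight of a directed edge (source, target) is the number of events on
#' that ordered pair. All events must belong to one (modality, fiscal year)
#' stratum.
#'
#' @param events data.frame of shared-use events
#'   (see [detect_shared_use()]).
#' @return object of class `shared_use_network`: list with `nodes`
#'   (character), `edges` (data.frame `source`, `target`, `weight`),
#'   `modality`, `fiscal_year`, and derived counts `n`, `m`.
#' @export
build_network <- function(events) {
  events <- as.data.frame(events)
  if (nrow(events) > 0) {
    if (length(unique(events$modality)) > 1L ||
        length(unique(events$fiscal_year)) > 1L) {
      stop_shareduse("events mix strata; build one network per ",
                     "(modality, fiscal_year)",
                     class = "shareduse_stratum_error")
    }
    if (any(events$source_facility_id == events$target_facility_id)) {
      stop_shareduse("self-loop event (source == target)",
                     class = "shareduse_validation_error")
    }
    agg <- stats::aggregate(
      list(weight = rep(1L, nrow(events))),
      by = list(source = events$source_facility_id,
                target = events$target_facility_id), FUN = sum)
    agg <- agg[order(agg$source, agg$target), , drop = FALSE]
    rownames(agg) <- NULL
    nodes <- sort(unique(c(agg$source, agg$target)))
    modality <- events$modality[1]
    fy <- events$fiscal_year[1]
  } else {
    agg <- data.frame(source = character(), target = character(),
                      weight = integer(), stringsAsFactors = FALSE)
    nodes <- character()
    modality <- NA_character_
    fy <- NA_integer_
  }
  structure(list(nodes = nodes, edges = agg, modality = modality,
                 fiscal_year = fy, n = length(nodes), m = nrow(agg)),
            class = "shared_use_network")
}

#' @export
print.shared_use_network <- function(x, ...) {
  cat("<shared_use_network> ", x$modality, " FY", x$fiscal_year,
      ": n=", x$n, " facilities, m=", x$m, " directed edges, ",
      sum(x$edges$weight), " events\n", sep = "")
  invisible(x)
}

#' Directed network density
#'
#' The proportion of realized referral connections among all possible
#' ordered facility pairs: `m / (n * (n - 1))`, unweighted, self-loops
#' excluded. Undefined (NA with a warning) for networks with fewer than two
#' nodes.
#'
#' @param network a [build_network()] object.
#' @return numeric in `[0, 1]`, or `NA` when undefined.
#' @export
network_density <- function(network) {
  stopifnot(inherits(network, "shared_use_network"))
  if (network$n < 2L) {
    warning("density undefined for networks with fewer than 2 nodes")
    return(NA_real_)
  }
  network$m / (network$n * (network$n - 1))
}

#' Dyad census of a directed network
#'
#' Counts connected unordered facility pairs by type: `mutual` (both
#' directions present) and `asymmetric` (exactly one direction).
#'
#' @param network a [build_network()] object.
#' @return list with integers `mutual` and `asymmetric`.
#' @export
dyad_census <- function(network) {
  stopifnot(inherits(network, "shared_use_network"))
  e <- network$edges
  if (nrow(e) == 0L) return(list(mutual = 0L, asymmetric = 0L))
  key <- ifelse(e$source < e$target,
                paste(e$source, e$target, sep = "\r"),
                paste(e$target, e$source, sep = "\r"))
  tab <- table(key)
  list(mutual = sum(tab == 2L), asymmetric = sum(tab == 1L))
}

#' Dyadic (or edge-wise) reciprocity
#'
#' With `a` mutual dyads and `b + c` asymmetric dyads, the dyadic convention
#' (default) returns `a / (a + b + c)`: the proportion of connected facility
#' pairs linked in both directions. The edge-wise convention returns
#' `2a / (2a + b + c)`: the proportion of directed edges that are
#' reciprocated. Weights are ignored (the census is unweighted). Undefined
#' (NA with a warning) when the network has no connected dyad.
#'
#' @param network a [build_network()] object.
#' @param convention `"dyadic"` or `"edgewise"`.
#' @return numeric in `[0, 1]`, or `NA` when undefined.
#' @export
network_reciprocity <- function(network,
                                convention = c("dyadic", "edgewise")) {
  convention <- match.arg(convention)
  cen <- dyad_census(network)
  tot <- cen$mutual + cen$asymmetric
  if (tot == 0L) {
    warning("reciprocity undefined: no connected dyads")
    return(NA_real_)
  }
  if (convention == "dyadic") {
    cen$mutual / tot
  } else {
    2 * cen$mutual / (2 * cen$mutual + cen$asymmetric)
  }
}

# Symmetric adjacency matrix of the undirected projection (w_ij = sum of the
# two directed weights); sum(A) == 2W. Weighted = FALSE uses unit directed
# weights.
.sym_adjacency <- function(network, weighted = TRUE) {
  n <- network$n
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  e <- network$edges
  if (nrow(e)) {
    w <- if (weighted) e$weight else rep(1, nrow(e))
    for (i in seq_len(nrow(e))) {
      A[e$source[i], e$target[i]] <- A[e$source[i], e$target[i]] + w[i]
      A[e$target[i], e$source[i]] <- A[e$target[i], e$source[i]] + w[i]
    }
  }
  A
}

.modularity_matrix <- function(A) {
  # Q(membership) = sum over same-community (i,j) of B_ij, with
  # B = (A - k k' / 2W) / 2W; self-pairs included (B_ii from degrees).
  W2 <- sum(A)
  if (W2 == 0) return(matrix(0, nrow(A), ncol(A)))
  k <- rowSums(A)
  (A - outer(k, k) / W2) / W2
}

.modularity_value <- function(A, membership) {
  B <- .modularity_matrix(A)
  same <- outer(membership, membership, "==")
  sum(B[same])
}

#' Newman-Girvan modularity of a partition
#'
#' Evaluates `Q = (1/2W) * sum_ij [w_ij - k_i k_j / 2W] delta(c_i, c_j)` on
#' the symmetrized undirected projection of the network (`w_ij` = sum of the
#' two directed weights, `W` = total undirected weight).
#'
#' @param network a [build_network()] object.
#' @param membership named vector (or a `louvain_communities()` result)
#'   assigning every node to a community.
#' @param weighted use edge weights (default) or the unweighted projection.
#' @return numeric `Q` in `[-1, 1]`.
#' @export
network_modularity <- function(network, membership, weighted = TRUE) {
  stopifnot(inherits(network, "shared_use_network"))
  if (inherits(membership, "shared_use_partition")) {
    membership <- membership$membership
  }
  missing_nodes <- setdiff(network$nodes, names(membership))
  if (length(missing_nodes)) {
    stop_shareduse("partition is missing node(s): ",
                   paste(missing_nodes, collapse = ", "),
                   class = "shareduse_partition_error")
  }
  if (network$n == 0L) return(0)
  A <- .sym_adjacency(network, weighted)
  .modularity_value(A, as.integer(factor(membership[network$nodes])))
}

# One Louvain level: greedy local moving on symmetric matrix A (which may
# carry self-loops from aggregation; diag counts twice in degrees via
# sum(A) bookkeeping). Returns integer membership 1..K.
.louvain_level <- function(A, order_idx, resolution, init = NULL) {
  n <- nrow(A)
  W2 <- sum(A)
  if (W2 == 0) return(seq_len(n))
  W <- W2 / 2
  k <- rowSums(A)
  comm <- if (is.null(init)) seq_len(n) else as.integer(init)
  Ktot <- as.vector(tapply(k, factor(comm, levels = seq_len(max(comm))), sum))
  Ktot[is.na(Ktot)] <- 0
  repeat {
    moved <- FALSE
    for (i in order_idx) {
      ci <- comm[i]
      Ai <- A[i, ]
      Ai[i] <- 0
      # links from i to each community
      L <- tapply(Ai, comm, sum)
      L[is.na(L)] <- 0
      Ktot_excl <- Ktot
      Ktot_excl[ci] <- Ktot_excl[ci] - k[i]
      base_links <- if (as.character(ci) %in% names(L)) L[[as.character(ci)]] else 0
      cand <- unique(comm[Ai > 0])
      cand <- cand[cand != ci]
      # detaching to a fresh singleton is also a legal move (relevant when
      # starting from a non-singleton partition)
      empty <- max(comm) + 1L
      if (sum(comm == ci) > 1L) cand <- c(cand, empty)
      if (!length(cand)) next
      best_gain <- 0
      best_c <- ci
      for (cc in cand) {
        links_cc <- if (cc == empty) 0 else L[[as.character(cc)]]
        ktot_cc <- if (cc == empty) 0 else Ktot_excl[cc]
        gain <- (links_cc - base_links) / W -
          resolution * k[i] * (ktot_cc - Ktot_excl[ci]) / (2 * W^2)
        if (gain > best_gain + 1e-10) {
          best_gain <- gain
          best_c <- cc
        }
      }
      if (best_c != ci && best_gain > 1e-10) {
        if (best_c == empty) Ktot <- c(Ktot, 0)
        Ktot[ci] <- Ktot[ci] - k[i]
        Ktot[best_c] <- Ktot[best_c] + k[i]
        comm[i] <- best_c
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.integer(factor(comm))
}

.aggregate_adjacency <- function(A, membership) {
  K <- max(membership)
  Z <- matrix(0, nrow(A), K)
  Z[cbind(seq_len(nrow(A)), membership)] <- 1
  t(Z) %*% A %*% Z
}

#' Louvain community detection
#'
#' Two-phase Louvain modularity optimization on the symmetrized weighted
#' projection of the directed network: greedy local moving (modularity gain
#' threshold 1e-10, node order shuffled deterministically from `seed`) until
#' no move improves, then aggregation of communities into super-nodes,
#' repeated until a full pass no longer improves Q. The modularity after
#' each pass is recorded (attribute `pass_Q`) and is non-decreasing; no
#' guarantee is made that the final Q exceeds that of the one-community
#' partition.
#'
#' @param network a [build_network()] object.
#' @param seed integer; controls the node-order shuffles and restart
#'   initializations (default 0).
#' @param resolution resolution parameter `gamma` scaling the null-model
#'   term during optimization (1 = classical modularity). Reported Q is
#'   always classical (`gamma` = 1).
#' @param n_restarts number of independent optimization runs (default 20):
#'   the first starts from the classical all-singleton partition, later
#'   restarts begin local moving from a random initial partition
#'   (multistart basin hopping; greedy local moving alone has strict local
#'   optima even on very small graphs). The run with the highest Q is
#'   returned.
#' @return object of class `shared_use_partition`: list with `membership`
#'   (named integer vector) and `Q`; attribute `pass_Q` holds Q after each
#'   pass of the winning run.
#' @export
louvain_communities <- function(network, seed = 0L, resolution = 1.0,
                                n_restarts = 20L) {
  stopifnot(inherits(network, "shared_use_network"), n_restarts >= 1L)
  n <- network$n
  if (n == 0L) {
    return(structure(list(membership = stats::setNames(integer(), character()),
                          Q = 0), class = "shared_use_partition"))
  }
  A0 <- .sym_adjacency(network, weighted = TRUE)
  if (n == 1L || sum(A0) == 0) {
    memb <- stats::setNames(rep(1L, n), network$nodes)
    return(structure(list(membership = memb, Q = 0),
                     class = "shared_use_partition"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) NULL else {
      with_substream(seed, 100000L + r,
                     sample.int(sample.int(n, 1L), n, replace = TRUE))
    }
    run <- .louvain_run(A0, seed, r, resolution, init)
    if (is.null(best) || run$Q > best$Q + 1e-12) best <- run
  }
  membership <- stats::setNames(as.integer(factor(best$mapping)),
                                network$nodes)
  structure(list(membership = membership, Q = best$Q),
            class = "shared_use_partition", pass_Q = best$pass_Q)
}

# One full Louvain run (local moving + aggregation until convergence).
.louvain_run <- function(A0, seed, restart, resolution, init) {
  A <- A0
  mapping <- seq_len(nrow(A0))  # original node -> current-level community
  pass_Q <- numeric()
  prev_Q <- -Inf
  level <- 0L
  repeat {
    level <- level + 1L
    order_idx <- with_substream(seed, restart * 1000L + level,
                                sample.int(nrow(A)))
    memb <- .louvain_level(A, order_idx, resolution,
                           init = if (level == 1L) init else NULL)
    memb <- as.integer(factor(memb))
    mapping <- memb[mapping]
    Q <- .modularity_value(A0, mapping)
    pass_Q <- c(pass_Q, Q)
    n_comm <- max(memb)
    if (Q <= prev_Q + 1e-10 || n_comm == nrow(A)) break
    prev_Q <- Q
    A <- .aggregate_adjacency(A, memb)
  }
  list(mapping = mapping, Q = pass_Q[length(pass_Q)], pass_Q = pass_Q)
}

#' @export
print.shared_use_partition <- function(x, ...) {
  cat("<shared_use_partition> ", length(unique(x$membership)),
      " communities over ", length(x$membership), " nodes, Q = ",
      format(x$Q, digits = 4), "\n", sep = "")
  invisible(x)
}

# Restricted-growth-string enumeration of all set partitions of n items.
.all_partitions <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  prev <- .all_partitions(n - 1L)
  out <- list()
  for (r in seq_len(nrow(prev))) {
    row <- prev[r, ]
    mx <- max(row)
    for (g in seq_len(mx + 1L)) {
      out[[length(out) + 1L]] <- c(row, g)
    }
  }
  do.call(rbind, out)
}

#' Exhaustive-search modularity optimum (small networks)
#'
#' Enumerates every partition of the node set (restricted growth strings;
#' Bell(n) partitions) and returns the one maximizing weighted modularity.
#' Reference oracle for validating [louvain_communities()]; refuses
#' networks with more than 12 nodes.
#'
#' @param network a [build_network()] object with `n <= 12`.
#' @return a `shared_use_partition` with the optimal `membership` and `Q`.
#' @export
best_partition_exhaustive <- function(network) {
  stopifnot(inherits(network, "shared_use_network"), network$n <= 12L)
  n <- network$n
  if (n == 0L) {
    return(structure(list(membership = stats::setNames(integer(), character()),
                          Q = 0), class = "shared_use_partition"))
  }
  A <- .sym_adjacency(network, weighted = TRUE)
  B <- .modularity_matrix(A)
  P <- .all_partitions(n)
  # Q for partition row p: sum of B over same-community cells
  same_mask <- function(m) as.vector(outer(m, m, "=="))
  M <- t(apply(P, 1, same_mask))
  Qs <- as.vector(M %*% as.vector(B))
  best <- which.max(Qs)
  structure(list(membership = stats::setNames(P[best, ], network$nodes),
                 Q = Qs[best]), class = "shared_use_partition")
}

#' Export a network to GraphML or an edge-list TSV
#'
#' GraphML carries the directed edges with a `weight` attribute and, when a
#' partition is supplied, a `community` node attribute; the edge-list format
#' is a three-column TSV (`source`, `target`, `weight`).
#'
#' @param network a [build_network()] object.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @param partition optional `shared_use_partition` (or named membership
#'   vector) to attach as node attribute.
#' @return invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("graphml",
                                                     "edgelist_tsv"),
                           partition = NULL) {
  stopifnot(inherits(network, "shared_use_network"))
  format <- match.arg(format)
  if (format == "edgelist_tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  if (!is.null(partition)) {
    if (inherits(partition, "shared_use_partition")) {
      partition <- partition$membership
    }
    igraph::V(g)$community <- as.integer(partition[network$nodes])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
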