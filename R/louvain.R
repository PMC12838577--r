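# Dense symmetric weight-matrix view of a graph. Diagonal entries store
# twice the self-loop weight (so rowSums() gives the conventional weighted
# degree and sum() gives 2m); functional graphs have none at the top level,
# but aggregation below creates them.
as_weight_matrix <- function(graph) {
  if (is.matrix(graph)) {
    if (nrow(graph) != ncol(graph) ||
        !isTRUE(all.equal(unname(graph), unname(t(graph))))) {
      abort("weight matrix must be square and symmetric.",
            class = "spikesync_validation_error")
    }
    if (is.null(rownames(graph))) {
      rownames(graph) <- colnames(graph) <- sprintf("n%d", seq_len(nrow(graph)))
    }
    return(graph)
  }
  if (inherits(graph, "functional_graph") ||
      (is.data.frame(graph) && all(c("from", "to", "weight") %in% names(graph)))) {
    nodes <- attr(graph, "nodes") %||% sort(unique(c(graph$from, graph$to)))
    W <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    if (nrow(graph) > 0) {
      i <- match(graph$from, nodes)
      j <- match(graph$to, nodes)
      W[cbind(i, j)] <- W[cbind(i, j)] + graph$weight
      W[cbind(j, i)] <- W[cbind(j, i)] + graph$weight
    }
    return(W)
  }
  abort("expected a functional_graph, edge data frame, or weight matrix.",
        class = "spikesync_validation_error")
}

modularity_matrix <- function(A, membership, gamma = 1) {
  m2 <- sum(A)
  if (m2 <= 0) {
    abort("modularity is undefined for an empty (edgeless) graph.",
          class = "spikesync_analysis_error")
  }
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    sigma_in <- sum(A[idx, idx])
    sigma_tot <- sum(k[idx])
    q <- q + sigma_in / m2 - gamma * (sigma_tot / m2)^2
  }
  q
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ Sigma_in(c) / 2m  -  gamma * (Sigma_tot(c) / 2m)^2 ]`,
#' where `Sigma_in(c)` is twice the internal edge weight of community `c`,
#' `Sigma_tot(c)` its total weighted degree and `2m` the graph's total
#' weighted degree. Isolated-node communities contribute 0. Any partition
#' that puts all nodes in one community has `Q = 1 - gamma`.
#'
#' @param graph A [functional_edges()] graph, an edge data frame
#'   (`from`, `to`, `weight`), or a symmetric weight matrix.
#' @param partition A `partition` object, a tibble with `node`/`community`
#'   columns, or a named vector mapping node to community label.
#' @param gamma Resolution parameter (> 0, default 1).
#' @return Modularity Q, a number in `[-1, 1]`.
#' @export
modularity <- function(graph, partition, gamma = 1) {
  if (gamma <= 0) {
    abort("gamma must be positive.", class = "spikesync_validation_error")
  }
  A <- as_weight_matrix(graph)
  memb <- partition_labels(partition)
  missing_nodes <- setdiff(rownames(A), names(memb))
  if (length(missing_nodes) > 0) {
    abort(sprintf("partition does not cover node(s): %s",
                  paste(missing_nodes, collapse = ", ")),
          class = "spikesync_validation_error")
  }
  modularity_matrix(A, as.integer(factor(memb[rownames(A)])), gamma)
}

partition_labels <- function(partition) {
  if (inherits(partition, "partition") ||
      (is.data.frame(partition) &&
         all(c("node", "community") %in% names(partition)))) {
    return(setNames(partition$community, partition$node))
  }
  if (!is.null(names(partition))) return(partition)
  abort("partition must be a partition tibble or a named node->community vector.",
        class = "spikesync_validation_error")
}

# One Louvain level: local moving on the (possibly aggregated) graph A
# until a full pass makes no move. Returns membership renumbered by first
# appearance and the modularity trace (one value per pass; non-decreasing).
louvain_one_level <- function(A, gamma) {
  n <- nrow(A)
  memb <- seq_len(n)
  k <- rowSums(A)
  m2 <- sum(A)
  m <- m2 / 2
  sigma_tot <- k  # indexed by community id (= initial node index)
  q_trace <- modularity_matrix(A, memb, gamma)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- memb[i]
      nb <- which(A[i, ] > 0)
      nb <- nb[nb != i]
      # weight from i into each candidate community
      s_by_comm <- if (length(nb) > 0) {
        vapply(split(A[i, nb], memb[nb]), sum, numeric(1))
      } else {
        numeric(0)
      }
      cand <- as.integer(names(s_by_comm))
      # take i out of its community, then compare staying vs each candidate
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      s_cur <- if (ci %in% cand) s_by_comm[[as.character(ci)]] else 0
      gain_cur <- s_cur / m - gamma * sigma_tot[ci] * k[i] / (2 * m^2)
      gains <- if (length(cand) > 0) {
        as.numeric(s_by_comm) / m -
          gamma * sigma_tot[cand] * k[i] / (2 * m^2)
      } else {
        numeric(0)
      }
      best <- ci
      eps <- 1e-12
      if (length(gains) > 0 && max(gains) > gain_cur + eps) {
        top <- cand[gains >= max(gains) - eps]
        best <- min(top)  # deterministic tie-break: lowest label
      }
      sigma_tot[best] <- sigma_tot[best] + k[i]
      if (best != ci) {
        memb[i] <- best
        moved <- TRUE
      }
    }
    q_trace <- c(q_trace, modularity_matrix(A, memb, gamma))
    if (!moved) break
  }
  list(membership = match(memb, unique(memb)), q_trace = q_trace,
       n_comms = length(unique(memb)))
}

aggregate_graph <- function(A, membership) {
  B <- rowsum(A, membership)
  B <- rowsum(t(B), membership)
  dimnames(B) <- list(seq_len(nrow(B)), seq_len(nrow(B)))
  B
}

#' Louvain community detection
#'
#' Greedy weighted-modularity maximisation: repeated local-moving passes
#' (nodes visited in a seed-shuffled order, each moved to the neighbouring
#' community with the largest positive modularity gain) alternate with
#' aggregation of communities into super-nodes, until a full level yields
#' no further improvement. Ties in the gain keep the current community, or
#' take the lowest community label, making runs reproducible given the
#' seed. Modularity never decreases across passes; the recorded trace is
#' exposed for verification.
#'
#' @inheritParams modularity
#' @param seed Integer seed controlling the node visit orders.
#' @param n_restarts Number of independent greedy runs (visit orders
#'   derived from `seed`); the best-modularity partition is returned.
#'   Greedy modularity maximisation can stall in local optima on small or
#'   noisy graphs, and a handful of restarts removes most of them at
#'   negligible cost.
#' @return A `partition`: tibble (`node`, `community`) with community
#'   labels renumbered 1..K by first appearance in node order, and
#'   attributes `modularity`, `gamma`, `seed`, `q_trace` (modularity per
#'   local-moving pass of the winning run; non-decreasing).
#' @export
#' @examples
#' edges <- tibble::tibble(from = c("a", "a", "b", "c", "c", "d"),
#'                         to   = c("b", "b2", "b2", "d", "d2", "d2"),
#'                         weight = 1)
#' louvain(edges)
louvain <- function(graph, gamma = 1, seed = 0L, n_restarts = 5L) {
  if (gamma <= 0) {
    abort("gamma must be positive.", class = "spikesync_validation_error")
  }
  W <- as_weight_matrix(graph)
  if (sum(W) <= 0) {
    abort("Louvain requires a graph with at least one edge (modularity is undefined on an edgeless graph).",
          class = "spikesync_analysis_error")
  }
  set.seed(as.integer(seed))
  restart_seeds <- sample.int(.Machine$integer.max - 1L,
                              max(1L, n_restarts))
  best <- NULL
  for (rs in restart_seeds) {
    cand <- louvain_single_run(W, gamma, rs)
    if (is.null(best) || cand$q > best$q + 1e-12) best <- cand
  }
  out <- tibble(node = rownames(W), community = best$labels)
  structure(out, class = c("partition", class(out)),
            modularity = best$q, gamma = gamma, seed = as.integer(seed),
            q_trace = best$q_trace)
}

louvain_single_run <- function(W, gamma, run_seed) {
  set.seed(as.integer(run_seed))
  memb_orig <- seq_len(nrow(W))
  A <- W
  q_trace <- numeric(0)
  repeat {
    lev <- louvain_one_level(A, gamma)
    q_trace <- c(q_trace, lev$q_trace)
    memb_orig <- lev$membership[memb_orig]
    if (lev$n_comms == nrow(A)) break
    A <- aggregate_graph(A, lev$membership)
  }
  labels <- match(memb_orig, unique(memb_orig))
  list(labels = labels, q = modularity_matrix(W, labels, gamma),
       q_trace = q_trace)
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities, Q = %.4f (gamma = %g)\n",
              nrow(x), length(unique(x$community)),
              attr(x, "modularity"), attr(x, "gamma")))
  NextMethod()
}

#' @export
#' @method glance partition
glance.partition <- function(x, ...) {
  tibble(n_nodes = nrow(x),
         n_communities = length(unique(x$community)),
         modularity = attr(x, "modularity"),
         gamma = attr(x, "gamma"),
         seed = attr(x, "seed"))
}

#' @export
#' @method tidy partition
tidy.partition <- function(x, ...) {
  as_tibble(x)
}
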