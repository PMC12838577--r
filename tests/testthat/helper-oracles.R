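# Independent oracles and small fixture builders used across tests.
# Each oracle is a direct, naive realisation of a definition, kept free of
# the package's own code paths.

# Full dynamic-programming table for the unit-cost edit distance.
dp_levenshtein <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  D <- matrix(0L, na + 1, nb + 1)
  D[, 1] <- 0:na
  D[1, ] <- 0:nb
  if (na > 0 && nb > 0) {
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                               D[i, j] + (a[i] != b[j]))
      }
    }
  }
  D[na + 1, nb + 1]
}

# Double-loop evaluation of the modularity definition.
brute_modularity <- function(W, memb, gamma = 1) {
  k <- rowSums(W)
  m2 <- sum(W)
  q <- 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      if (memb[i] == memb[j]) {
        q <- q + W[i, j] / m2 - gamma * k[i] * k[j] / m2^2
      }
    }
  }
  unname(q)
}

# All set partitions of n items as restricted-growth membership vectors.
set_partitions <- function(n) {
  res <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(integer(0), 0L)
  res
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment.
enum_mw_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  ranks <- rank(c(x, y))
  ux_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(ranks[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  lower <- mean(u_all <= ux_obs + 1e-9)
  upper <- mean(u_all >= ux_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns.
enum_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Edge tibble for a unit-weight clique over the given node names.
clique_edges <- function(nodes, weight = 1) {
  p <- t(utils::combn(nodes, 2))
  tibble::tibble(from = p[, 1], to = p[, 2], weight = weight)
}

# Random spike recording: Poisson trains with random rates.
random_recording <- function(n_channels = 5, duration = 10,
                             max_rate = 3) {
  spikes <- purrr::map(seq_len(n_channels), function(i) {
    n <- stats::rpois(1, stats::runif(1, 0.5, max_rate) * duration)
    if (n == 0) return(NULL)
    tibble::tibble(channel = sprintf("c%02d", i),
                   time_s = sort(stats::runif(n, 0, duration - 1e-9)))
  })
  trial_recording(dplyr::bind_rows(spikes), duration,
                  channels = sprintf("c%02d", seq_len(n_channels)))
}

# Random symmetric synchrony-like matrix with the package's class.
random_sync_matrix <- function(n = 10) {
  r <- matrix(stats::runif(n * n, -1, 1), n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  structure(r, class = c("synchrony_matrix", "matrix"),
            bin_width_s = 0.1, min_rate_hz = 0.1)
}

# Random connected-ish weighted graph as a weight matrix.
random_weight_graph <- function(n = 8, p_edge = 0.5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        W[i, j] <- W[j, i] <- stats::runif(1, 0.1, 1)
      }
    }
  }
  if (sum(W) == 0) W[1, 2] <- W[2, 1] <- 1
  dimnames(W) <- list(sprintf("v%d", 1:n), sprintf("v%d", 1:n))
  W
}
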