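new_rank_test <- function(method, statistic, n, n1 = NA_integer_,
                          n2 = NA_integer_, p_value, z, r, exact, ties,
                          note = NA_character_) {
  structure(
    list(method = method, statistic = statistic, n = n, n1 = n1, n2 = n2,
         p_value = p_value, z = z, effect_size_r = r, exact = exact,
         ties = ties, note = note),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> %s\n", x$method))
  cat(sprintf("  statistic = %g, n = %s, p = %.4g (%s), Z = %.3f, r = %.3f\n",
              x$statistic,
              if (is.na(x$n1)) x$n else sprintf("%d+%d", x$n1, x$n2),
              x$p_value, if (x$exact) "exact" else "normal approx.",
              x$z, x$effect_size_r))
  if (!is.na(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' @export
#' @method tidy rank_test
tidy.rank_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, n = x$n,
         n1 = x$n1, n2 = x$n2, p_value = x$p_value, z = x$z,
         effect_size_r = x$effect_size_r, exact = x$exact, ties = x$ties)
}

#' @export
#' @method glance rank_test
glance.rank_test <- function(x, ...) tidy.rank_test(x, ...)

# Two-sided p by doubling the smaller tail of a discrete null distribution
# given as support/probability vectors, capped at 1.
doubled_tail_p <- function(stat, support, prob, tol = 1e-9) {
  lower <- sum(prob[support <= stat + tol])
  upper <- sum(prob[support >= stat - tol])
  min(1, 2 * min(lower, upper))
}

#' Exact Mann-Whitney U test with effect size
#'
#' Two-sided Mann-Whitney U test for independent samples. The reported
#' statistic is `U = min(U_x, U_y)`. Without ties and for
#' `n1 + n2 <= exact_max_n`, the exact p doubles the smaller tail of the
#' exact null distribution of U (capped at 1). With ties, mid-ranks are
#' used and the exact p is obtained by enumerating all group assignments
#' when `choose(n1 + n2, n1) <= max_enum`; otherwise (and for large
#' samples) the normal approximation is used with a notice. The effect
#' size is `r = |Z| / sqrt(n1 + n2)` with
#' `Z = (U - n1 n2 / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)`; by default no
#' continuity correction and no tie correction enter Z, so r depends only
#' on (U, n1, n2).
#'
#' @param x,y Numeric samples (both nonempty).
#' @param exact_max_n Largest `n1 + n2` for which the exact tie-free path
#'   is used (default 25).
#' @param max_enum Enumeration budget for the tied exact path.
#' @param continuity Apply a 0.5 continuity correction in Z.
#' @param tie_correction Apply the tie-corrected variance in Z.
#' @return A `rank_test` object.
#' @export
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4, 5), c(10, 11, 12, 13, 14))
mann_whitney_exact <- function(x, y, exact_max_n = 25, max_enum = 1e5,
                               continuity = FALSE, tie_correction = FALSE) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty.",
          class = "spikesync_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("samples must not contain missing values.",
          class = "spikesync_validation_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ranks <- rank(c(x, y))  # mid-ranks under ties
  ux <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  u <- min(ux, uy)
  has_ties <- anyDuplicated(c(x, y)) > 0

  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 * (n + 1) / 12
  if (tie_correction) {
    tie_tab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                              (n * (n - 1)))
  }
  cc <- if (continuity) sign(u - mu) * (-0.5) else 0
  z <- if (sig2 > 0) (u - mu + cc) / sqrt(sig2) else 0
  r <- abs(z) / sqrt(n)

  exact <- FALSE; note <- NA_character_
  if (!has_ties && n <= exact_max_n) {
    support <- 0:(n1 * n2)
    prob <- stats::dwilcox(support, n1, n2)
    p <- doubled_tail_p(ux, support, prob)
    exact <- TRUE
  } else if (has_ties && choose(n, n1) <= max_enum) {
    combos <- combn(n, n1)
    u_all <- colSums(matrix(ranks[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    tab <- table(u_all)
    support <- as.numeric(names(tab))
    prob <- as.numeric(tab) / length(u_all)
    p <- doubled_tail_p(ux, support, prob)
    exact <- TRUE
    note <- "ties present: exact p by permutation enumeration with mid-ranks."
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    note <- "normal approximation (sample too large or too many tied arrangements)."
    inform(paste("mann_whitney_exact:", note))
  }
  new_rank_test("Mann-Whitney U", statistic = u, n = n, n1 = n1, n2 = n2,
                p_value = p, z = z, r = r, exact = exact,
                ties = has_ties, note = note)
}

#' Exact Wilcoxon signed-rank test with effect size
#'
#' Two-sided Wilcoxon signed-rank test for paired samples. Zero
#' differences are dropped (n counts the remainder). The statistic is
#' `W = min(W+, W-)` over the ranks of |differences| (mid-ranks under
#' ties). For `n <= exact_max_n` the exact p doubles the smaller tail of
#' the null distribution of W+ over all 2^n equally likely sign patterns
#' (computed by convolution over the rank weights, which handles tied
#' ranks exactly); larger n falls back to the normal approximation with a
#' notice. The effect size is `r = |Z| / sqrt(n)` with
#' `Z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` (no continuity or tie
#' correction by default).
#'
#' @param x Paired sample, or the vector of differences when `y` is NULL.
#' @param y Optional second paired sample (same length as `x`).
#' @param exact_max_n Largest n for the exact path (default 20).
#' @param continuity Apply a 0.5 continuity correction in Z.
#' @param tie_correction Apply the tie-corrected variance in Z.
#' @return A `rank_test` object.
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(c(5, 6, 7), c(1, 2, 3))
wilcoxon_signed_rank_exact <- function(x, y = NULL, exact_max_n = 20,
                                       continuity = FALSE,
                                       tie_correction = FALSE) {
  x <- as.double(x)
  if (!is.null(y)) {
    y <- as.double(y)
    if (length(x) != length(y)) {
      abort("paired samples must have equal length.",
            class = "spikesync_validation_error")
    }
    d <- x - y
  } else {
    d <- x
  }
  if (anyNA(d)) {
    abort("differences must not contain missing values.",
          class = "spikesync_validation_error")
  }
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("all differences are zero; the signed-rank test is undefined.",
          class = "spikesync_analysis_error")
  }
  if (n_dropped > 0) {
    inform(sprintf("wilcoxon_signed_rank_exact: dropped %d zero difference(s).",
                   n_dropped))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  w_minus <- sum(rk) - w_plus
  w <- min(w_plus, w_minus)
  has_ties <- anyDuplicated(abs(d)) > 0

  mu <- n * (n + 1) / 4
  sig2 <- n * (n + 1) * (2 * n + 1) / 24
  if (tie_correction) {
    tie_tab <- table(abs(d))
    sig2 <- sig2 - sum(tie_tab^3 - tie_tab) / 48
  }
  cc <- if (continuity) sign(w - mu) * (-0.5) else 0
  z <- if (sig2 > 0) (w - mu + cc) / sqrt(sig2) else 0
  r <- abs(z) / sqrt(n)

  exact <- FALSE; note <- NA_character_
  if (n <= exact_max_n) {
    dist <- signed_rank_null(rk)
    p <- doubled_tail_p(w_plus, dist$support, dist$prob)
    exact <- TRUE
    if (has_ties) {
      note <- "tied |differences|: exact null uses mid-rank weights."
    }
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
    note <- "normal approximation (n too large for enumeration)."
    inform(paste("wilcoxon_signed_rank_exact:", note))
  }
  new_rank_test("Wilcoxon signed-rank", statistic = w, n = n,
                p_value = p, z = z, r = r, exact = exact,
                ties = has_ties, note = note)
}

# Null distribution of W+ = sum of rank weights with independent fair
# signs: convolution on a grid of doubled ranks (integers even for
# mid-ranks). Equivalent to enumerating all 2^n sign patterns.
signed_rank_null <- function(ranks) {
  w2 <- as.integer(round(2 * ranks))  # doubled ranks are integers
  total <- sum(w2)
  prob <- numeric(total + 1)
  prob[1] <- 1
  for (w in w2) {
    shifted <- c(numeric(w), prob[seq_len(total + 1 - w)])
    prob <- (prob + shifted) / 2
  }
  list(support = (0:total) / 2, prob = prob)
}
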