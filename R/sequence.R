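#' Canonical affiliation sequence of a partition
#'
#' Scans the fixed node order and assigns symbol `A` to the first community
#' encountered, `B` to the second, and so on (`AA`, `AB`, ... beyond 26).
#' Two partitions that are identical up to a permutation of community
#' labels therefore yield identical sequences, which is what makes
#' between-trial edit distances meaningful. Nodes absent from the partition
#' (inactive in that trial) receive the reserved symbol `"."`, which never
#' participates in canonical numbering, so sequence length is constant
#' across trials of one manifest.
#'
#' @param partition A `partition` (or node/community tibble, or named
#'   vector).
#' @param node_order Character vector of channel ids fixing the scan order;
#'   must contain every partitioned node. Defaults to the partition's nodes
#'   in lexicographic order.
#' @param inactive Reserved symbol for unpartitioned nodes.
#' @return Character vector of symbols, one per entry of `node_order`, with
#'   attribute `node_order`.
#' @export
#' @examples
#' p <- tibble::tibble(node = c("n1", "n2", "n3", "n4"),
#'                     community = c(7, 7, 3, 3))
#' paste(affiliation_sequence(p, c("n1", "n2", "n3", "n4")), collapse = "")
affiliation_sequence <- function(partition, node_order = NULL,
                                 inactive = ".") {
  memb <- partition_labels(partition)
  node_order <- node_order %||% sort(names(memb))
  missing_nodes <- setdiff(names(memb), node_order)
  if (length(missing_nodes) > 0) {
    abort(sprintf("node_order lacks partitioned node(s): %s",
                  paste(missing_nodes, collapse = ", ")),
          class = "spikesync_validation_error")
  }
  raw <- memb[node_order]  # NA for inactive nodes
  seen <- unique(raw[!is.na(raw)])
  sym <- canonical_symbols(length(seen))
  out <- ifelse(is.na(raw), inactive, sym[match(raw, seen)])
  structure(as.character(out), node_order = node_order)
}

canonical_symbols <- function(n) {
  if (n == 0) return(character(0))
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}

#' Levenshtein edit distance
#'
#' Minimum number of single-symbol insertions, deletions and substitutions
#' (unit costs) transforming one symbol sequence into another. Sequences
#' may be character vectors of symbols or single strings (compared
#' character-wise). Computed via base R's exact generalized edit distance
#' after mapping symbols to unique characters, so multi-character symbols
#' count as single edits.
#'
#' @param a,b Symbol sequences (character vectors, possibly empty) or
#'   single strings.
#' @return Integer distance.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
levenshtein <- function(a, b) {
  a <- as_symbol_vector(a)
  b <- as_symbol_vector(b)
  symbols <- unique(c(a, b))
  if (length(symbols) == 0) return(0L)
  # map symbols into a private unicode block: one char per symbol
  chars <- intToUtf8(0x2800 + seq_along(symbols) - 1L, multiple = TRUE)
  sa <- paste(chars[match(a, symbols)], collapse = "")
  sb <- paste(chars[match(b, symbols)], collapse = "")
  as.integer(adist(sa, sb)[1, 1])
}

as_symbol_vector <- function(x) {
  x <- as.character(x)
  if (length(x) == 1 && !is.na(x) && nchar(x) > 1) {
    x <- strsplit(x, "")[[1]]
  }
  x[!is.na(x)]
}

#' Between-trial network similarity
#'
#' `1 - levenshtein(a, b) / max(length(a), length(b))`, in `[0, 1]`;
#' equals 1 exactly when the canonical sequences are identical. With the
#' fixed node order and reserved inactive symbol of
#' [affiliation_sequence()], both sequences have the same length n and the
#' normalisation reduces to `1 - d/n`.
#'
#' @param seq_a,seq_b Affiliation sequences (at least one nonempty).
#' @return Similarity in `[0, 1]`.
#' @export
network_similarity <- function(seq_a, seq_b) {
  a <- as_symbol_vector(seq_a)
  b <- as_symbol_vector(seq_b)
  if (length(a) == 0 && length(b) == 0) {
    abort("both sequences are empty; similarity is undefined.",
          class = "spikesync_analysis_error")
  }
  1 - levenshtein(a, b) / max(length(a), length(b))
}
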