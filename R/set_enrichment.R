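# Exact hypergeometric tails, BH adjustment, pairwise gene-list overlap
# tests and exclusive multi-list intersection tabulation.

#' Exact hypergeometric tail probability
#'
#' Upper tail P(X >= k) (or lower tail P(X <= k)) for X ~
#' Hypergeometric(N, K, n): the probability of observing at least
#' (at most) `k` category members in a draw of `n` from a universe of
#' `N` containing `K` category members.  The sum is accumulated in
#' log-space so extreme tails (p ~ 1e-300) remain accurate.
#'
#' @param N Universe size.
#' @param K Number of category members ("successes") in the universe.
#' @param n Draw size.
#' @param k Observed category members in the draw.
#' @param lower Use the lower tail (depletion) instead of the upper.
#' @return The tail probability, a single number in (0, 1].
#' @export
hypergeom_tail <- function(N, K, n, k, lower = FALSE) {
  if (length(N) != 1 || length(K) != 1 || length(n) != 1 || length(k) != 1) {
    stop("hypergeom_tail takes scalar parameters", call. = FALSE)
  }
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n)) {
    stop(sprintf(
      "inconsistent hypergeometric parameters: N=%s K=%s n=%s k=%s",
      N, K, n, k), call. = FALSE)
  }
  lo <- max(0, n - (N - K))
  hi <- min(K, n)
  # k below the support minimum: the lower-tail event is impossible
  if (lower && k < lo) return(0)
  j <- if (lower) lo:k else max(k, lo):hi
  lp <- dhyper(j, K, N - K, n, log = TRUE)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1; order-preserving on the input
#' order statistics.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether `set_a` is enriched for members of `set_b` within a
#' stated universe: N = |universe|, K = |set_b|, n = |set_a|,
#' k = |set_a intersect set_b|.  Genes outside the universe are clipped
#' with a warning (platform/universe mismatches are common between
#' probe-derived lists and gene models).
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector defining the universe.
#' @param lower Test depletion (lower tail) instead of enrichment.
#' @return A one-row tibble with `N`, `K`, `n`, `k`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe, lower = FALSE) {
  universe <- unique(universe)
  a <- unique(set_a)
  b <- unique(set_b)
  dropped <- length(setdiff(a, universe)) + length(setdiff(b, universe))
  if (dropped > 0) {
    warning(sprintf("%d gene(s) outside the universe dropped", dropped),
            call. = FALSE)
    a <- intersect(a, universe)
    b <- intersect(b, universe)
  }
  k <- length(intersect(a, b))
  tibble(N = length(universe), K = length(b), n = length(a), k = k,
         p = hypergeom_tail(length(universe), length(b), length(a), k,
                            lower = lower))
}

#' Exclusive intersections of named gene sets
#'
#' Tabulates every non-empty membership pattern over the supplied sets
#' (the Venn/UpSet partition): patterns are mutually exclusive and
#' their counts sum to the size of the union.
#'
#' @param named_sets Named list of character vectors.
#' @return A tibble with one logical column per input set, plus `count`
#'   and a `gene_ids` list column.
#' @export
exclusive_intersections <- function(named_sets) {
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets)))) {
    stop("all sets must be named", call. = FALSE)
  }
  elems <- sort(unique(unlist(named_sets, use.names = FALSE)))
  member <- vapply(named_sets, function(s) elems %in% s,
                   logical(length(elems)))
  if (length(elems) == 1L) member <- matrix(member, nrow = 1)
  key <- apply(member, 1, paste, collapse = "")
  out <- lapply(split(seq_along(elems), key), function(idx) {
    pat <- member[idx[1], ]
    c(as.list(pat), list(count = length(idx), gene_ids = list(elems[idx])))
  })
  df <- do.call(rbind, lapply(out, function(row) {
    as_tibble(row[names(named_sets)])
  }))
  df$count <- unname(vapply(out, function(row) row$count, integer(1)))
  df$gene_ids <- unname(lapply(out, function(row) row$gene_ids[[1]]))
  rownames(df) <- NULL
  as_tibble(df)
}
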