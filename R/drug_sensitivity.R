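# NCI-60 style machinery: correlate every drug sensitivity profile with
# every gene expression profile across a cell-line panel, compile
# per-drug FDR-significant gene sets split by correlation sign, and
# rank drugs by hypergeometric cistrome enrichment of those sets.

#' Correlate drug sensitivity with gene expression across a panel
#'
#' Pearson correlation (and two-sided p) for every (drug, gene) pair
#' over the cell lines shared by the two matrices, using
#' pairwise-complete observations; pairs with fewer than `min_pairs`
#' mutually present lines are skipped (`NA`).  Within each drug the
#' p-values are BH-adjusted across genes (`q`); set
#' `fdr_family = "global"` to adjust across all pairs instead.
#'
#' @param drug_matrix Drugs x lines numeric matrix (Z-scores).
#' @param expr_matrix Genes x lines numeric matrix (Z-scores).
#' @param min_pairs Minimum mutually non-missing lines per pair.
#' @param fdr_family `"within_drug"` (default) or `"global"`.
#' @return A tibble with `drug_id`, `gene_id`, `r`, `p`, `q`, `n_lines`.
#' @export
correlate_drug_genes <- function(drug_matrix, expr_matrix, min_pairs = 3,
                                 fdr_family = c("within_drug", "global")) {
  fdr_family <- match.arg(fdr_family)
  lines <- intersect(colnames(drug_matrix), colnames(expr_matrix))
  if (!length(lines)) stop("no shared cell lines", call. = FALSE)
  dm <- drug_matrix[, lines, drop = FALSE]
  em <- expr_matrix[, lines, drop = FALSE]
  r <- suppressWarnings(cor(t(dm), t(em), use = "pairwise.complete.obs"))
  npairs <- (!is.na(dm)) %*% t(!is.na(em))
  r[npairs < min_pairs] <- NA
  df <- npairs - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[is.na(r)] <- NA
  q <- p
  if (fdr_family == "within_drug") {
    for (i in seq_len(nrow(p))) q[i, ] <- bh_adjust(p[i, ])
  } else {
    q[] <- bh_adjust(as.vector(p))
  }
  out <- tibble(
    drug_id = rep(rownames(dm), times = ncol(r)),
    gene_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r),
    p = as.vector(p),
    q = as.vector(q),
    n_lines = as.vector(npairs)
  )
  out[order(out$drug_id, out$gene_id), ]
}

#' Per-drug positive and negative correlated gene sets
#'
#' For each drug: the genes whose expression correlates with its
#' sensitivity at `q <= fdr`, split by correlation sign.
#'
#' @param correlations Tibble from [correlate_drug_genes()].
#' @param fdr FDR threshold on `q`.
#' @return A tibble with `drug_id`, `positive` and `negative` (list
#'   columns of gene ids), `fdr_threshold`.
#' @export
build_drug_gene_sets <- function(correlations, fdr = 0.1) {
  drugs <- unique(correlations$drug_id)
  sig <- !is.na(correlations$q) & correlations$q <= fdr
  pos <- split(correlations$gene_id[sig & correlations$r > 0],
               correlations$drug_id[sig & correlations$r > 0])
  neg <- split(correlations$gene_id[sig & correlations$r < 0],
               correlations$drug_id[sig & correlations$r < 0])
  tibble(
    drug_id = drugs,
    positive = lapply(drugs, function(d) as.character(pos[[d]])),
    negative = lapply(drugs, function(d) as.character(neg[[d]])),
    fdr_threshold = fdr
  )
}

#' Rank drugs by cistrome enrichment of their correlated gene sets
#'
#' For every (drug, direction) pair with a non-empty gene set: the
#' upper-tail hypergeometric probability of the observed overlap with
#' the cistrome genes, drawn from the expression universe.  P-values
#' are BH-adjusted across all tested rows, the table is sorted by
#' adjusted p and filtered to `adj_p <= fdr`.
#'
#' @param drug_sets Tibble from [build_drug_gene_sets()].
#' @param cistrome_genes Character vector; must lie within `universe`.
#' @param universe Character vector of all genes in the expression
#'   matrix.
#' @param fdr Enrichment FDR threshold on `adj_p` (set to 1 to keep all
#'   tested rows).
#' @return A tibble with `drug_id`, `direction`, `n_correlated`,
#'   `n_cistrome`, `overlap`, `overlap_pct`, `p`, `adj_p`, ordered by
#'   `adj_p`.
#' @export
rank_cistrome_enrichment <- function(drug_sets, cistrome_genes, universe,
                                     fdr = 0.01) {
  universe <- unique(universe)
  cistrome <- intersect(unique(cistrome_genes), universe)
  N <- length(universe)
  K <- length(cistrome)
  rows <- list()
  for (i in seq_len(nrow(drug_sets))) {
    for (direction in c("positive", "negative")) {
      genes <- drug_sets[[direction]][[i]]
      if (!length(genes)) next
      extra <- setdiff(genes, universe)
      if (length(extra)) {
        stop(sprintf("drug set for %s contains %d gene(s) outside universe",
                     drug_sets$drug_id[i], length(extra)), call. = FALSE)
      }
      n <- length(genes)
      k <- length(intersect(genes, cistrome))
      rows[[length(rows) + 1]] <- tibble(
        drug_id = drug_sets$drug_id[i],
        direction = direction,
        n_correlated = n,
        n_cistrome = K,
        overlap = k,
        overlap_pct = 100 * k / n,
        p = hypergeom_tail(N, K, n, k)
      )
    }
  }
  if (!length(rows)) {
    return(tibble(drug_id = character(), direction = character(),
                  n_correlated = integer(), n_cistrome = integer(),
                  overlap = integer(), overlap_pct = double(),
                  p = double(), adj_p = double()))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$adj_p, out$p), ]
  out[out$adj_p <= fdr, ]
}
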