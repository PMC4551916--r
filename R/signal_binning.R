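# The 81-bin metagene model: 40 x 100 bp bins centered on the TSS,
# one gene-body bin, 40 x 100 bp bins centered on the TTS.  Genes
# shorter than 4100 bp (whose TSS and TTS flanks would collide with the
# body bin) are excluded rather than truncated.

#' Metagene bin schema
#'
#' @param bins_per_anchor Number of 100 bp bins centered on each of the
#'   TSS and TTS (the 4 kb anchor window is
#'   `bins_per_anchor * bin_size` wide).
#' @param bin_size Bin width in bp.
#' @param min_gene_length Minimum gene length; shorter genes are
#'   excluded.  The default 4100 leaves at least a 100 bp gene-body bin
#'   between the two 2 kb inner flanks.
#' @return A list with `bins_per_anchor`, `bin_size`,
#'   `min_gene_length`, `total_bins`, `anchor_flank`.
#' @export
bin_schema <- function(bins_per_anchor = 40, bin_size = 100,
                       min_gene_length = 4100) {
  list(
    bins_per_anchor = as.integer(bins_per_anchor),
    bin_size = as.integer(bin_size),
    min_gene_length = as.integer(min_gene_length),
    total_bins = as.integer(2 * bins_per_anchor + 1),
    anchor_flank = as.integer(bins_per_anchor * bin_size / 2)
  )
}

#' Bin intervals for one gene
#'
#' Returns the 81 (by default) bin intervals of a gene, ordered 5' to
#' 3' in gene orientation: the TSS anchor window
#' `[tss - flank, tss + flank)` split into 100 bp bins, one gene-body
#' bin over the residual interior, then the TTS anchor window.  For
#' minus-strand genes the bins are mirror-ordered so bin 1 is always
#' the most 5' bin.  Genes shorter than the schema minimum are excluded
#' (returns `NULL` with a message, not an error).
#'
#' @param gene One-row gene tibble or list with `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param schema A [bin_schema()].
#' @return A tibble with `bin`, `chrom`, `start`, `end`, `section`
#'   (`"tss"`, `"body"`, `"tts"`), or `NULL` for a too-short gene.
#' @export
make_bins <- function(gene, schema = bin_schema()) {
  len <- gene$end - gene$start
  if (len < schema$min_gene_length) {
    message(sprintf("gene %s (length %d) shorter than %d bp: excluded",
                    gene$gene_id, len, schema$min_gene_length))
    return(NULL)
  }
  fl <- schema$anchor_flank
  bs <- schema$bin_size
  nb <- schema$bins_per_anchor
  if (gene$strand == "+") {
    tss <- gene$start
    tts <- gene$end
    tss_starts <- seq(tss - fl, by = bs, length.out = nb)
    tts_starts <- seq(tts - fl, by = bs, length.out = nb)
    starts <- c(tss_starts, tss + fl, tts_starts)
    ends <- c(tss_starts + bs, tts - fl, tts_starts + bs)
  } else {
    tss <- gene$end
    tts <- gene$start
    # 5'-most bin has the highest genomic coordinate on the minus strand
    tss_ends <- seq(tss + fl, by = -bs, length.out = nb)
    tts_ends <- seq(tts + fl, by = -bs, length.out = nb)
    starts <- c(tss_ends - bs, tts + fl, tts_ends - bs)
    ends <- c(tss_ends, tss - fl, tts_ends)
  }
  tibble(
    bin = seq_len(schema$total_bins),
    chrom = gene$chrom,
    start = as.integer(starts),
    end = as.integer(ends),
    section = c(rep("tss", nb), "body", rep("tts", nb))
  )
}

# Sum of value * overlap-width of a track over a set of bins.
.track_bin_sums <- function(track, bins_gr) {
  sums <- numeric(length(bins_gr))
  if (!nrow(track) || !length(bins_gr)) return(sums)
  tgr <- .gr(track$chrom, track$start, track$end)
  hits <- .fo(tgr, bins_gr)
  if (!length(hits)) return(sums)
  ov <- width(pintersect(tgr[queryHits(hits)], bins_gr[subjectHits(hits)]))
  contrib <- rowsum(track$value[queryHits(hits)] * ov, subjectHits(hits))
  sums[as.integer(rownames(contrib))] <- contrib[, 1]
  sums
}

#' Mean log signal per bin for one gene
#'
#' Mean track value over each bin — positions without track coverage
#' count as 0 in the mean — then log-transformed as `log(x + 1)`.
#'
#' @param track Signal track tibble (see [read_signal_track()]).
#' @param bins Bin tibble from [make_bins()].
#' @return Numeric vector of length `nrow(bins)`.
#' @export
bin_signal <- function(track, bins) {
  bgr <- .gr(bins$chrom, bins$start, bins$end)
  sums <- .track_bin_sums(track, bgr)
  log1p(sums / (bins$end - bins$start))
}

#' Bin matrix: genes x metagene bins of log binding signal
#'
#' Applies the bin schema to every sufficiently long gene and averages
#' the track over every bin in one pass.
#'
#' @param genes Gene model tibble.
#' @param track Signal track tibble.
#' @param schema A [bin_schema()].
#' @return A list with `matrix` (genes x `total_bins`, rownames are
#'   gene ids, values `log(mean_signal + 1)`) and `excluded` (ids of
#'   genes below the minimum length).
#' @export
bin_matrix <- function(genes, track, schema = bin_schema()) {
  len <- genes$end - genes$start
  keep <- len >= schema$min_gene_length
  kept <- genes[keep, ]
  nb <- schema$total_bins
  if (!nrow(kept)) {
    return(list(matrix = matrix(numeric(0), 0, nb,
                                dimnames = list(NULL, NULL)),
                excluded = genes$gene_id[!keep]))
  }
  all_bins <- do.call(rbind, lapply(seq_len(nrow(kept)), function(i) {
    b <- suppressMessages(make_bins(kept[i, ], schema))
    b$gene_idx <- i
    b
  }))
  bgr <- .gr(all_bins$chrom, all_bins$start, all_bins$end)
  sums <- .track_bin_sums(track, bgr)
  means <- sums / (all_bins$end - all_bins$start)
  mat <- matrix(0, nrow(kept), nb,
                dimnames = list(kept$gene_id, paste0("bin", seq_len(nb))))
  mat[cbind(all_bins$gene_idx, all_bins$bin)] <- log1p(means)
  list(matrix = mat, excluded = genes$gene_id[!keep])
}

#' Per-bin correlation between binding signal and expression
#'
#' Pearson correlation (and two-sided p) between each bin's log-signal
#' column and log expression over the genes shared between the matrix
#' and the expression vector.  Constant columns get `NA` correlations.
#'
#' @param mat Bin matrix (genes x bins), e.g. `bin_matrix()$matrix`.
#' @param expression Named numeric vector of (logged) expression.
#' @return A tibble with `bin`, `r`, `p`, `mean_signal`.
#' @export
per_bin_correlation <- function(mat, expression) {
  shared <- intersect(rownames(mat), names(expression))
  if (length(shared) < 3) {
    stop("need >= 3 genes shared between bin matrix and expression",
         call. = FALSE)
  }
  m <- mat[shared, , drop = FALSE]
  e <- expression[shared]
  stats <- lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    if (sd(x) == 0 || sd(e) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(x, e, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  })
  tibble(
    bin = seq_len(ncol(m)),
    r = vapply(stats, `[[`, 0, "r"),
    p = vapply(stats, `[[`, 0, "p"),
    mean_signal = colMeans(m)
  )
}

#' Average feature profile around the TSS
#'
#' For every strand-oriented offset in `[-flank, flank)`, the mean
#' number of features covering `tss + offset` across genes, divided by
#' the curve maximum when `normalize` is `TRUE` (skipped when the
#' profile is all zero).
#'
#' @param features Peak-like tibble with `chrom`, `start`, `end`.
#' @param genes Gene model tibble (supplies TSS and strand).
#' @param flank Profile half-width in bp.
#' @param normalize Divide by the maximum.
#' @return A tibble with `offset` and `value`.
#' @export
tss_profile <- function(features, genes, flank = 2000, normalize = TRUE) {
  n_off <- 2L * flank
  acc <- numeric(n_off + 1L)  # diff-array; last slot absorbs run-offs
  if (nrow(features) && nrow(genes)) {
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    wgr <- .gr(genes$chrom, tss - flank, tss + flank)
    fgr <- .gr(features$chrom, features$start, features$end)
    hits <- .fo(fgr, wgr)
    for (h in seq_along(hits)) {
      f <- queryHits(hits)[h]
      g <- subjectHits(hits)[h]
      lo <- max(features$start[f], tss[g] - flank)
      hi <- min(features$end[f], tss[g] + flank)
      if (genes$strand[g] == "+") {
        o1 <- lo - tss[g]
        o2 <- hi - tss[g]
      } else {
        o1 <- tss[g] - hi
        o2 <- tss[g] - lo
      }
      i1 <- o1 + flank + 1L
      i2 <- o2 + flank + 1L
      acc[i1] <- acc[i1] + 1
      acc[i2] <- acc[i2] - 1
    }
  }
  cov <- cumsum(acc)[seq_len(n_off)]
  value <- if (nrow(genes)) cov / nrow(genes) else cov
  if (normalize && any(value > 0)) value <- value / max(value)
  tibble(offset = seq(-flank, flank - 1L), value = value)
}

#' Methylation as a function of distance to the nearest TSS
#'
#' Signed, strand-oriented distance from each CpG to its nearest TSS,
#' filtered to `[-flank, flank]`, with a degree-`degree` polynomial fit
#' for the smoothed profile curve.
#'
#' @param cpgs CpG tibble.
#' @param genes Gene model tibble.
#' @param flank Maximum |distance| kept, in bp.
#' @param degree Polynomial degree of the fitted curve.
#' @return A list with `points` (tibble `distance`, `methylation`),
#'   `curve` (tibble `distance`, `fitted`; zero rows when too few
#'   points) and `model` (the `lm` fit or `NULL`).
#' @export
methylation_distance_profile <- function(cpgs, genes, flank = 1000,
                                         degree = 3) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  dist <- rep(NA_real_, nrow(cpgs))
  for (ch in unique(cpgs$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    ci <- which(cpgs$chrom == ch)
    ts <- sort(tss[gi])
    sense <- genes$strand[gi][order(tss[gi])]
    pos <- cpgs$position[ci]
    right <- findInterval(pos, ts) + 1L
    left <- right - 1L
    d_left <- ifelse(left >= 1, pos - ts[pmax(left, 1)], Inf)
    d_right <- ifelse(right <= length(ts), ts[pmin(right, length(ts))] - pos,
                      Inf)
    use_left <- abs(d_left) <= abs(d_right)
    nearest <- ifelse(use_left, pmax(left, 1L), pmin(right, length(ts)))
    signed <- pos - ts[nearest]
    signed <- ifelse(sense[nearest] == "-", -signed, signed)
    dist[ci] <- signed
  }
  keep <- !is.na(dist) & abs(dist) <= flank
  points <- tibble(distance = dist[keep],
                   methylation = cpgs$methylation_pct[keep])
  model <- NULL
  curve <- tibble(distance = numeric(0), fitted = numeric(0))
  if (nrow(points) > degree + 1 && length(unique(points$distance)) > degree) {
    model <- lm(methylation ~ poly(distance, degree), data = points)
    grid <- tibble(distance = seq(-flank, flank, length.out = 201))
    curve <- tibble(distance = grid$distance,
                    fitted = predict(model, newdata = grid))
  }
  list(points = points, curve = curve, model = model)
}
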