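# Promoter-window state annotation: filter peaks, build +/-1 kb TSS
# windows, merge methylation replicates, assign each gene a
# combinatorial epigenomic state (N/H/F/C) and query the sub-cistrome
# lattice.

#' Filter peaks by length and signal intensity
#'
#' Removes peaks that are very large or of low intensity: a peak is kept
#' only if its length is at most `max_length` *and* its signal value is
#' at least `min_signal`.  Defaults reproduce the standard cistrome
#' clean-up (drop peaks > 100 kb or signal < 2).
#'
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param max_length Maximum peak length in bp.
#' @param min_signal Minimum signal value.
#' @return The surviving peaks, input order preserved, with attributes
#'   `n_removed` (count filtered out) and `mean_length` (mean length of
#'   survivors, `NaN` when none survive).
#' @export
filter_peaks <- function(peaks, max_length = 100000, min_signal = 2) {
  len <- peaks$end - peaks$start
  keep <- len <= max_length & peaks$signal_value >= min_signal
  out <- peaks[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "mean_length") <- mean(len[keep])
  out
}

#' Build fixed-flank TSS windows
#'
#' One window per gene spanning `[tss - flank, tss + flank)`.  The TSS
#' is the gene start for plus-strand genes and the gene end for
#' minus-strand genes; unstranded genes are rejected.
#'
#' @param genes Gene model tibble (see [read_gene_models()]).
#' @param flank Half-width of the window in bp (default 1000, i.e. a
#'   2 kb promoter window).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `tss`, `strand`.
#' @export
make_tss_windows <- function(genes, flank = 1000) {
  if (flank <= 0) stop("flank must be > 0", call. = FALSE)
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("all genes must be stranded (+ or -)", call. = FALSE)
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  start <- as.integer(tss - flank)
  if (any(start < 0L)) {
    warning("TSS window truncated at chromosome start for some genes",
            call. = FALSE)
    start <- pmax(start, 0L)
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = start, end = as.integer(tss + flank),
         tss = as.integer(tss), strand = genes$strand)
}

#' Does a peak overlap a TSS window?
#'
#' A peak counts as overlapping when at least `min_fraction` of the
#' *peak* length (never the window length) falls inside the window.
#' The boundary is inclusive: an overlap fraction of exactly
#' `min_fraction` returns `TRUE`.  Different chromosomes return `FALSE`.
#'
#' @param peak A one-row peak tibble or list with `chrom`, `start`, `end`.
#' @param window A one-row window tibble or list with `chrom`, `start`,
#'   `end`.
#' @param min_fraction Minimum fraction of the peak inside the window.
#' @return Logical scalar.
#' @export
peak_overlaps_window <- function(peak, window, min_fraction = 0.25) {
  if (peak$chrom != window$chrom) return(FALSE)
  ov <- min(peak$end, window$end) - max(peak$start, window$start)
  if (ov <= 0) return(FALSE)
  ov / (peak$end - peak$start) >= min_fraction
}

# Vectorized flag: for each window, is there >= 1 peak whose overlap
# fraction (of peak length) meets min_fraction?
.window_flags <- function(windows, peaks, min_fraction) {
  flags <- rep(FALSE, nrow(windows))
  if (!nrow(peaks) || !nrow(windows)) return(flags)
  wgr <- .gr(windows$chrom, windows$start, windows$end)
  pgr <- .gr(peaks$chrom, peaks$start, peaks$end)
  hits <- .fo(pgr, wgr)
  if (!length(hits)) return(flags)
  ov <- width(pintersect(pgr[queryHits(hits)], wgr[subjectHits(hits)]))
  frac <- ov / width(pgr)[queryHits(hits)]
  flags[unique(subjectHits(hits)[frac >= min_fraction])] <- TRUE
  flags
}

#' Merge two methylation replicates
#'
#' Keeps only CpG positions present in both replicates with at least
#' `min_reads` coverage in each; the merged methylation percentage is
#' the arithmetic mean of the two replicates and the merged coverage the
#' minimum of the two.
#'
#' @param rep1,rep2 CpG tibbles (see [read_methylation()]).
#' @param min_reads Minimum read coverage required in each replicate.
#' @return A merged CpG tibble sorted by (chrom, position).
#' @export
merge_methylation_replicates <- function(rep1, rep2, min_reads = 10) {
  k1 <- paste(rep1$chrom, rep1$position)
  k2 <- paste(rep2$chrom, rep2$position)
  i2 <- match(k1, k2)
  keep <- !is.na(i2) & rep1$coverage >= min_reads &
    rep2$coverage[i2] >= min_reads
  out <- tibble(
    chrom = rep1$chrom[keep],
    position = rep1$position[keep],
    methylation_pct = (rep1$methylation_pct[keep] +
                         rep2$methylation_pct[i2[keep]]) / 2,
    coverage = pmin(rep1$coverage[keep], rep2$coverage[i2[keep]])
  )
  out[order(out$chrom, out$position), ]
}

#' Mean methylation of CpGs inside a window
#'
#' Unweighted mean of `methylation_pct` over CpGs whose position falls
#' inside the half-open window; `NA` when no CpG falls inside (the
#' window has no detectable methylation, state `C = f`).
#'
#' @param cpgs CpG tibble.
#' @param window One-row tibble or list with `chrom`, `start`, `end`.
#' @return A single numeric in \[0, 100\], or `NA`.
#' @export
window_mean_methylation <- function(cpgs, window) {
  inside <- cpgs$chrom == window$chrom &
    cpgs$position >= window$start & cpgs$position < window$end
  if (!any(inside)) return(NA_real_)
  mean(cpgs$methylation_pct[inside])
}

# Mean methylation per window, vectorized over windows.
.window_meth <- function(windows, cpgs) {
  out <- rep(NA_real_, nrow(windows))
  if (!nrow(cpgs) || !nrow(windows)) return(out)
  wgr <- .gr(windows$chrom, windows$start, windows$end)
  cgr <- .gr(cpgs$chrom, cpgs$position, cpgs$position + 1L)
  hits <- .fo(cgr, wgr)
  if (!length(hits)) return(out)
  sums <- rowsum(cpgs$methylation_pct[queryHits(hits)], subjectHits(hits))
  counts <- rowsum(rep(1, length(hits)), subjectHits(hits))
  idx <- as.integer(rownames(sums))
  out[idx] <- sums[, 1] / counts[, 1]
  out
}

#' Annotate genes with combinatorial epigenomic states
#'
#' For each gene, flags the +/-`flank` TSS window for factor binding
#' (`N`), the histone mark (`H`) and open chromatin (`F`): `t` when at
#' least one peak of the respective set overlaps the window by the 25%
#' peak-fraction rule, else `f`.  The methylation axis `C` is `f` when
#' no CpG falls in the window, `l` when the mean methylation is below
#' `meth_cut` and `h` otherwise (a mean of exactly `meth_cut` is high).
#'
#' Peaks are expected to be already filtered ([filter_peaks()]) and the
#' CpGs already replicate-merged ([merge_methylation_replicates()]).
#'
#' @param genes Gene model tibble.
#' @param factor_peaks,mark_peaks,open_peaks Peak tibbles for the factor
#'   of interest, the histone mark and the open-chromatin assay.
#' @param cpgs Merged CpG tibble (may have zero rows, meaning no
#'   detectable CpGs anywhere; must not be `NULL`).
#' @param flank TSS window half-width in bp.
#' @param min_overlap_frac Peak-fraction overlap threshold.
#' @param meth_cut Low/high methylation cut in percent.
#' @return A tibble with columns `gene_id`, `N`, `H`, `F` (each
#'   `"t"`/`"f"`), `C` (`"l"`/`"h"`/`"f"`), `mean_methylation`.
#' @export
annotate_states <- function(genes, factor_peaks, mark_peaks, open_peaks,
                            cpgs, flank = 1000, min_overlap_frac = 0.25,
                            meth_cut = 30) {
  if (is.null(cpgs)) {
    stop("methylation input is missing (pass a zero-row CpG table if no ",
         "CpGs were detected)", call. = FALSE)
  }
  if (any(genes$end <= genes$start)) {
    stop("genes with zero-length intervals", call. = FALSE)
  }
  windows <- make_tss_windows(genes, flank = flank)
  n_flag <- .window_flags(windows, factor_peaks, min_overlap_frac)
  h_flag <- .window_flags(windows, mark_peaks, min_overlap_frac)
  f_flag <- .window_flags(windows, open_peaks, min_overlap_frac)
  meth <- .window_meth(windows, cpgs)
  c_state <- ifelse(is.na(meth), "f", ifelse(meth < meth_cut, "l", "h"))
  tibble(
    gene_id = genes$gene_id,
    N = ifelse(n_flag, "t", "f"),
    H = ifelse(h_flag, "t", "f"),
    F = ifelse(f_flag, "t", "f"),
    C = c_state,
    mean_methylation = meth
  )
}

#' Construct a sub-cistrome query
#'
#' A query fixes each of the four state axes to a concrete value or
#' leaves it `"i"` (independent, matches anything).  `N`, `H`, `F` take
#' `t`/`f`/`i`; `C` takes `l`/`h`/`f`/`i`.
#'
#' @param N,H,F,C Axis values.
#' @return A named character vector of class `cistra_query`.
#' @export
subset_query <- function(N = "i", H = "i", F = "i", C = "i") {
  q <- c(N = N, H = H, F = F, C = C)
  ok <- c(N %in% c("t", "f", "i"), H %in% c("t", "f", "i"),
          F %in% c("t", "f", "i"), C %in% c("l", "h", "f", "i"))
  if (!all(ok)) {
    stop("invalid query axis value: ", paste(q[!ok], collapse = ", "),
         call. = FALSE)
  }
  structure(q, class = "cistra_query")
}

#' Parse a query from its compact string form
#'
#' @param x A string like `"t,i,t,l"` giving the N, H, F, C axes in
#'   order.
#' @return A `cistra_query`.
#' @export
parse_query <- function(x) {
  parts <- trimws(strsplit(x, ",")[[1]])
  if (length(parts) != 4) {
    stop("query must have 4 comma-separated axes (N,H,F,C)", call. = FALSE)
  }
  subset_query(parts[1], parts[2], parts[3], parts[4])
}

#' Select the genes matching a sub-cistrome query
#'
#' A gene matches when its observed state equals the query on every
#' non-independent axis; `"i"` matches any observed value.
#'
#' @param states State tibble from [annotate_states()].
#' @param query A `cistra_query` (or anything [subset_query()] accepts
#'   as a named vector with entries N, H, F, C).
#' @return Character vector of matching gene ids.
#' @export
select_subset <- function(states, query) {
  keep <- rep(TRUE, nrow(states))
  for (axis in c("N", "H", "F", "C")) {
    if (query[[axis]] != "i") keep <- keep & states[[axis]] == query[[axis]]
  }
  states$gene_id[keep]
}

#' Enumerate the full sub-cistrome lattice
#'
#' With the factor axis fixed (by default to bound genes, `N = t`),
#' emits every query over `{t,f,i}` for H and F and `{l,h,f,i}` for C —
#' 36 queries — each with its gene set and size.  Empty subsets are
#' flagged, not dropped.
#'
#' @param states State tibble from [annotate_states()].
#' @param fixed_N Value the N axis is fixed to (`"t"`, `"f"` or `"i"`).
#' @return A tibble with columns `N`, `H`, `F`, `C`, `query` (compact
#'   string), `gene_ids` (list column), `n`, `empty`.
#' @export
enumerate_subsets <- function(states, fixed_N = "t") {
  grid <- expand.grid(H = c("t", "f", "i"), F = c("t", "f", "i"),
                      C = c("l", "h", "f", "i"),
                      stringsAsFactors = FALSE)
  sets <- lapply(seq_len(nrow(grid)), function(i) {
    select_subset(states, subset_query(fixed_N, grid$H[i], grid$F[i],
                                       grid$C[i]))
  })
  tibble(
    N = fixed_N, H = grid$H, F = grid$F, C = grid$C,
    query = paste(fixed_N, grid$H, grid$F, grid$C, sep = ","),
    gene_ids = sets,
    n = lengths(sets),
    empty = lengths(sets) == 0L
  )
}

#' Mutually exclusive ("unique") gene lists for a set of queries
#'
#' For each supplied query, returns its gene set minus the union of all
#' the *other* supplied queries' gene sets.
#'
#' @param states State tibble from [annotate_states()].
#' @param queries Named list of queries (see [subset_query()]).
#' @return Named list of character vectors, one per query.
#' @export
unique_subset_genes <- function(states, queries) {
  sets <- lapply(queries, function(q) select_subset(states, q))
  out <- lapply(seq_along(sets), function(i) {
    others <- unlist(sets[-i], use.names = FALSE)
    setdiff(sets[[i]], others)
  })
  names(out) <- names(queries)
  out
}

#' Classify interaction pairs by anchor overlap
#'
#' Counts how many interaction pairs have both, exactly one, or neither
#' anchor overlapping any of the supplied intervals (any nonzero overlap
#' counts).  The three counts always sum to the number of interactions.
#'
#' @param interactions Interaction tibble (see [read_interactions()]).
#' @param intervals A tibble with `chrom`, `start`, `end` (e.g. gene
#'   spans).
#' @return A named integer vector `c(both, one, none)`.
#' @export
anchor_overlap_counts <- function(interactions, intervals) {
  n <- nrow(interactions)
  if (!n) return(c(both = 0L, one = 0L, none = 0L))
  hit_any <- function(chrom, start, end) {
    if (!nrow(intervals)) return(rep(FALSE, length(chrom)))
    agr <- .gr(chrom, start, end)
    igr <- .gr(intervals$chrom, intervals$start, intervals$end)
    seq_along(chrom) %in% queryHits(.fo(agr, igr))
  }
  a <- hit_any(interactions$chrom_a, interactions$start_a, interactions$end_a)
  b <- hit_any(interactions$chrom_b, interactions$start_b, interactions$end_b)
  c(both = sum(a & b), one = sum(xor(a, b)), none = sum(!a & !b))
}
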