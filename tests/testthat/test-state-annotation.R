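test_that("peak filter removes long or weak peaks and is idempotent", {
  peaks <- peaks_tbl("chr1", c(0, 10000, 20000), c(150000, 15000, 25000),
                     signal = c(5, 1.5, 3))
  out <- filter_peaks(peaks)
  # length 150 kb removed, signal 1.5 removed, 5 kb @ 3 kept
  expect_equal(out$name, "p3")
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(attr(out, "mean_length"), 5000)
  again <- filter_peaks(out)
  expect_equal(again$name, out$name)
  expect_equal(attr(again, "n_removed"), 0L)
  # boundary: exactly 100 kb and exactly signal 2 survive
  edge <- peaks_tbl("chr1", 0, 100000, signal = 2)
  expect_equal(nrow(filter_peaks(edge)), 1L)
  expect_equal(nrow(filter_peaks(peaks_tbl("chr1", 1, 2, signal = 0))), 0L)
  expect_true(all(filter_peaks(random_peaks(100))$name %in%
                    random_peaks(100)$name))
})

test_that("TSS windows are strand-aware, fixed-length, and reject flank <= 0", {
  g <- genes_tbl(c("chr1", "chr1"), c(5000, 2000), c(9000, 8000),
                 c("+", "-"))
  w <- make_tss_windows(g, flank = 1000)
  expect_equal(w$start, c(4000L, 7000L))
  expect_equal(w$end, c(6000L, 9000L))
  expect_equal(w$tss, c(5000L, 8000L))
  expect_true(all(w$end - w$start == 2000L))
  expect_error(make_tss_windows(g, flank = 0), "flank")
  g$strand[1] <- "."
  expect_error(make_tss_windows(g), "stranded")
})

test_that("peak overlap uses the peak-length fraction with an inclusive boundary", {
  window <- list(chrom = "chr1", start = 4000, end = 6000)
  # 1000 bp peak with exactly 250 bp inside: fraction 0.25 counts
  expect_true(peak_overlaps_window(
    list(chrom = "chr1", start = 3250, end = 4250), window))
  expect_false(peak_overlaps_window(
    list(chrom = "chr1", start = 3249, end = 4249), window))
  expect_true(peak_overlaps_window(
    list(chrom = "chr1", start = 4500, end = 5500), window))
  expect_false(peak_overlaps_window(
    list(chrom = "chr2", start = 4500, end = 5500), window))
  # denominator is peak length, never window length: a 8000 bp peak
  # covering the whole 2000 bp window is only 25% inside -> still true
  expect_true(peak_overlaps_window(
    list(chrom = "chr1", start = 2000, end = 10000), window))
  expect_false(peak_overlaps_window(
    list(chrom = "chr1", start = 2000, end = 10001), window))
})

test_that("replicate merging requires coverage in both and averages", {
  r1 <- cpgs_tbl("chr1", c(100, 200, 300), c(40, 40, 10),
                 coverage = c(10, 9, 30))
  r2 <- cpgs_tbl("chr1", c(100, 200, 400), c(60, 60, 80),
                 coverage = c(12, 50, 40))
  m <- merge_methylation_replicates(r1, r2, min_reads = 10)
  expect_equal(m$position, 100L)          # 200 fails rep1 cov, 300/400 unshared
  expect_equal(m$methylation_pct, 50)     # mean of 40 and 60
  expect_equal(m$coverage, 10L)           # min of the two
  ident <- merge_methylation_replicates(r1, r1, min_reads = 10)
  expect_equal(ident$methylation_pct, r1$methylation_pct[r1$coverage >= 10])
})

test_that("window mean methylation is the unweighted mean over inside CpGs", {
  w <- list(chrom = "chr1", start = 4000, end = 6000)
  cpgs <- cpgs_tbl("chr1", c(4100, 5900), c(20, 40))
  expect_equal(window_mean_methylation(cpgs, w), 30)
  expect_equal(window_mean_methylation(cpgs_tbl("chr1", 4500, 45), w), 45)
  expect_true(is.na(window_mean_methylation(cpgs_tbl("chr1", 7000, 45), w)))
  # half-open boundary: position == start is in, position == end is out
  expect_equal(window_mean_methylation(cpgs_tbl("chr1", 4000, 10), w), 10)
  expect_true(is.na(window_mean_methylation(cpgs_tbl("chr1", 6000, 10), w)))
})

test_that("state annotation applies the flag rules and the 30% cut", {
  g <- genes_tbl(c("chr1", "chr1", "chr1"), c(10000, 30000, 50000),
                 c(20000, 40000, 60000), c("+", "+", "-"))
  # gene 1: factor peak half inside the window, no marks, no CpGs
  fac <- peaks_tbl("chr1", 9500, 10500)
  none <- peaks_tbl(character(), integer(), integer())
  s <- annotate_states(g, fac, none, none,
                       cpgs_tbl(character(), integer(), double()))
  expect_equal(unlist(s[1, c("N", "H", "F", "C")], use.names = FALSE),
               c("t", "f", "f", "f"))
  expect_equal(s$N, c("t", "f", "f"))

  # methylation boundary: 29.9 -> low, exactly 30 -> high
  cpgs <- cpgs_tbl("chr1", c(30100, 60100 - 1000), c(29.9, 30))
  s2 <- annotate_states(g, fac, none, none, cpgs)
  expect_equal(s2$C, c("f", "l", "h"))
  expect_equal(s2$mean_methylation, c(NA, 29.9, 30))
})

test_that("state annotation is invariant to peak and CpG input order", {
  ds <- generate_dataset(synthetic_config(seed = 11, n_genes = 150,
                                          n_drugs = 2))
  cpgs <- merge_methylation_replicates(ds$meth_rep1, ds$meth_rep2)
  base <- annotate_states(ds$genes, ds$factor_peaks, ds$mark_peaks,
                          ds$open_peaks, cpgs)
  shuf <- function(df, seed) withr::with_seed(seed, df[sample(nrow(df)), ])
  scrambled <- annotate_states(ds$genes, shuf(ds$factor_peaks, 1),
                               shuf(ds$mark_peaks, 2),
                               shuf(ds$open_peaks, 3), shuf(cpgs, 4))
  expect_equal(scrambled, base)
  bad <- ds$genes
  bad$end[1] <- bad$start[1]
  expect_error(annotate_states(bad, ds$factor_peaks, ds$mark_peaks,
                               ds$open_peaks, cpgs), "zero-length")
  expect_error(annotate_states(ds$genes, ds$factor_peaks, ds$mark_peaks,
                               ds$open_peaks, NULL), "methylation")
})

test_that("subset queries match manual enumeration on a hand-built fixture", {
  s <- states_tbl(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    N = c("t", "t", "t", "f", "t"),
    H = c("t", "f", "f", "t", "f"),
    F = c("t", "t", "f", "t", "t"),
    C = c("l", "h", "l", "l", "l")
  )
  # all-independent matches everything
  expect_equal(select_subset(s, subset_query()), s$gene_id)
  # N=t, F=t, C=l regardless of H: by hand, g1 and g5
  expect_equal(select_subset(s, parse_query("t,i,t,l")), c("g1", "g5"))
  # no gene has H=t together with C=h
  expect_equal(select_subset(s, parse_query("i,t,i,h")), character(0))
  # C axis: l matches only l, f only f
  expect_equal(select_subset(s, parse_query("i,i,i,h")), "g2")
  expect_equal(select_subset(s, parse_query("i,i,i,f")), character(0))
})

test_that("the sub-cistrome lattice has 36 queries with nesting and partition", {
  s <- random_states(80, seed = 5)
  cat <- enumerate_subsets(s, fixed_N = "t")
  expect_equal(nrow(cat), 36L)
  expect_equal(sum(duplicated(cat$query)), 0L)
  all_i <- cat[cat$H == "i" & cat$F == "i" & cat$C == "i", ]
  nt_universe <- s$gene_id[s$N == "t"]
  expect_setequal(all_i$gene_ids[[1]], nt_universe)
  # refinement nesting: fixing an axis shrinks the set
  g_ttl <- select_subset(s, parse_query("t,t,t,l"))
  g_tti <- select_subset(s, parse_query("t,t,i,i"))
  expect_true(all(g_ttl %in% g_tti))
  # concrete values on one axis partition the wildcard set
  h_parts <- lapply(c("t", "f"), function(v)
    select_subset(s, subset_query("t", v, "i", "i")))
  expect_setequal(unlist(h_parts), nt_universe)
  expect_equal(length(intersect(h_parts[[1]], h_parts[[2]])), 0L)
  c_parts <- lapply(c("l", "h", "f"), function(v)
    select_subset(s, subset_query("t", "i", "i", v)))
  expect_setequal(unlist(c_parts), nt_universe)
})

test_that("unique gene lists subtract the union of the other queries", {
  s <- states_tbl(
    gene_id = sprintf("g%d", 1:8),
    N = rep("t", 8),
    H = c("t", "t", "t", "f", "f", "f", "t", "f"),
    F = c("t", "f", "t", "t", "f", "t", "f", "f"),
    C = c("l", "l", "h", "l", "h", "h", "f", "f")
  )
  q <- list(Ht = parse_query("t,t,i,i"), Ft = parse_query("t,i,t,i"),
            Ch = parse_query("t,i,i,h"))
  # by manual set algebra: Ht = {1,2,3,7}, Ft = {1,3,4,6}, Ch = {3,5,6}
  u <- unique_subset_genes(s, q)
  expect_equal(u$Ht, c("g2", "g7"))
  expect_equal(u$Ft, "g4")
  expect_equal(u$Ch, "g5")
  # disjoint queries keep their full sets
  q2 <- list(a = parse_query("t,t,i,i"), b = parse_query("t,f,i,i"))
  u2 <- unique_subset_genes(s, q2)
  expect_setequal(u2$a, select_subset(s, q2$a))
  expect_setequal(u2$b, select_subset(s, q2$b))
  # identical queries annihilate each other
  u3 <- unique_subset_genes(s, list(x = q$Ht, y = q$Ht))
  expect_equal(lengths(u3), c(x = 0L, y = 0L))
})

test_that("anchor overlap counts match manual classification and conserve", {
  ints <- tibble::tibble(
    chrom_a = c("chr1", "chr1", "chr1", "chr9"),
    start_a = c(100, 100, 5000, 10),
    end_a = c(200, 200, 5100, 20),
    chrom_b = c("chr1", "chr2", "chr1", "chr9"),
    start_b = c(1000, 2000, 6000, 100),
    end_b = c(1100, 2100, 6100, 200)
  )
  spans <- tibble::tibble(chrom = c("chr1", "chr2"),
                          start = c(50, 950), end = c(1500, 1050))
  # by hand: pair 1 both anchors inside chr1 span; pair 2 anchor a only
  # (chr2 anchor misses the chr2 span); pair 3 neither; pair 4 chromosome
  # absent entirely
  counts <- anchor_overlap_counts(ints, spans)
  expect_equal(counts, c(both = 1L, one = 1L, none = 2L))
  expect_equal(sum(counts), nrow(ints))
  expect_equal(anchor_overlap_counts(ints[0, ], spans),
               c(both = 0L, one = 0L, none = 0L))
})
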