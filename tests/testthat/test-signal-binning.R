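test_that("a 4100 bp gene yields exactly 81 bins and 4099 bp is excluded", {
  g <- list(gene_id = "g1", chrom = "chr1", start = 100000L,
            end = 104100L, strand = "+")
  bins <- make_bins(g)
  expect_equal(nrow(bins), 81L)
  expect_equal(bins$end - bins$start,
               c(rep(100L, 40), 100L, rep(100L, 40)))  # body bin exactly 100
  expect_equal(bins$section[41], "body")
  # TSS flank tiles [tss - 2000, tss + 2000) exactly and in order
  expect_equal(bins$start[1], 98000L)
  expect_equal(bins$end[40], 102000L)
  expect_true(all(diff(bins$start[1:40]) == 100L))
  # TTS flank tiles [tts - 2000, tts + 2000)
  expect_equal(bins$start[42], 102100L)
  expect_equal(bins$end[81], 106100L)

  short <- list(gene_id = "g2", chrom = "chr1", start = 100000L,
                end = 104099L, strand = "+")
  expect_message(res <- make_bins(short), "excluded")
  expect_null(res)
})

test_that("minus-strand bins mirror so bin 1 is always most 5'", {
  g <- list(gene_id = "gm", chrom = "chr1", start = 50000L,
            end = 60000L, strand = "-")
  bins <- make_bins(g)
  expect_equal(nrow(bins), 81L)
  # TSS is the gene end; the most 5' bin sits furthest downstream in
  # genome coordinates: [tss + 1900, tss + 2000)
  expect_equal(bins$start[1], 61900L)
  expect_equal(bins$end[1], 62000L)
  # flank bins walk toward the gene, ending at tss - 2000
  expect_equal(bins$start[40], 58000L)
  expect_true(all(diff(bins$start[1:40]) == -100L))
  # body bin spans the residual interior
  expect_equal(bins$start[41], 52000L)
  expect_equal(bins$end[41], 58000L)
  # TTS flank ends at tts - 2000
  expect_equal(bins$end[42], 52000L)
  expect_equal(bins$start[81], 48000L)
  # flank bins are non-overlapping and tile their 4 kb windows
  expect_equal(sum(bins$end[1:40] - bins$start[1:40]), 4000L)
  expect_equal(sum(bins$end[42:81] - bins$start[42:81]), 4000L)
})

test_that("bin signal averages the track with zeros for uncovered gaps", {
  g <- list(gene_id = "g1", chrom = "chr1", start = 10000L,
            end = 14100L, strand = "+")
  bins <- make_bins(g)
  uniform <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L,
                            value = 3)
  expect_equal(bin_signal(uniform, bins), rep(log(4), 81))
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = double())
  expect_equal(bin_signal(empty, bins), rep(0, 81))

  # hand-built 3-interval track over the first two bins:
  # bin 1 = [8000, 8100): covered 8000-8050 at 2 -> mean (50*2)/100 = 1
  # bin 2 = [8100, 8200): 8100-8140 at 5 and 8140-8200 at 1
  #   -> mean (40*5 + 60*1)/100 = 2.6
  track <- tibble::tibble(chrom = "chr1",
                          start = c(7900L, 8100L, 8140L),
                          end = c(8050L, 8140L, 8200L),
                          value = c(2, 5, 1))
  sig <- bin_signal(track, bins)
  expect_equal(sig[1], log1p(1))
  expect_equal(sig[2], log1p(2.6))
  expect_equal(sig[3:81], rep(0, 79))
})

test_that("bin matrix rows cover exactly the long-enough genes", {
  genes <- genes_tbl("chr1", c(10000, 50000, 90000),
                     c(14100, 54099, 102000), c("+", "+", "-"),
                     gene_id = c("ok1", "short", "ok2"))
  track <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L,
                          value = 1)
  bm <- bin_matrix(genes, track)
  expect_equal(rownames(bm$matrix), c("ok1", "ok2"))
  expect_equal(bm$excluded, "short")
  expect_equal(ncol(bm$matrix), 81L)
  expect_equal(unname(bm$matrix[1, ]), rep(log(2), 81))
})

test_that("per-bin correlation finds a planted identity and is order-invariant", {
  withr::with_seed(14, {
    mat <- matrix(rlnorm(200 * 81), 200, 81,
                  dimnames = list(sprintf("g%d", 1:200),
                                  paste0("bin", 1:81)))
  })
  e <- mat[, 17]
  names(e) <- rownames(mat)
  prof <- per_bin_correlation(mat, e)
  expect_equal(prof$r[17], 1)
  expect_equal(which.max(abs(prof$r)), 17L)
  # gene order must not matter
  shuffled <- per_bin_correlation(mat[sample(200), ], e)
  expect_equal(shuffled$r, prof$r)
  # constant column: NA r, no crash
  mat2 <- mat
  mat2[, 5] <- 1
  prof2 <- per_bin_correlation(mat2, e)
  expect_true(is.na(prof2$r[5]))
  expect_error(per_bin_correlation(mat[1:2, ], e[1:2]), ">= 3 genes")
})

test_that("per-bin correlations are null-calibrated on independent data", {
  withr::with_seed(15, {
    mat <- matrix(rnorm(2000 * 81), 2000, 81,
                  dimnames = list(sprintf("g%d", 1:2000), NULL))
    e <- setNames(rnorm(2000), rownames(mat))
  })
  prof <- per_bin_correlation(mat, e)
  expect_true(all(abs(prof$r) < 0.1))
  expect_gt(mean(prof$p), 0.3)
  expect_lt(mean(prof$p <= 0.05), 0.15)
})

test_that("TSS profiles peak at the TSS for TSS-centered features", {
  genes <- genes_tbl("chr1", c(10000, 30000, 50000),
                     c(20000, 40000, 60000), c("+", "+", "-"))
  tss <- c(10000, 30000, 60000)
  feats <- peaks_tbl("chr1", tss - 100, tss + 100)
  prof <- tss_profile(feats, genes, flank = 2000)
  expect_equal(max(prof$value), 1)
  expect_equal(prof$value[prof$offset == 0], 1)
  expect_equal(prof$value[abs(prof$offset) > 100], rep(0, sum(abs(prof$offset) > 100)))
  # symmetric construction gives a symmetric profile
  left <- prof$value[prof$offset < 0 & prof$offset >= -100]
  right <- rev(prof$value[prof$offset >= 0 & prof$offset < 100])
  expect_equal(left, right)
  # no features: all-zero profile, normalization skipped
  none <- peaks_tbl(character(), integer(), integer())
  expect_equal(sum(tss_profile(none, genes)$value), 0)
})

test_that("methylation distance profile signs distances by strand", {
  genes <- genes_tbl("chr1", c(10000, 50000), c(20000, 60000), c("+", "-"))
  # one CpG 300 bp downstream of the plus TSS, one 400 bp upstream
  # (in gene orientation) of the minus TSS at 60000 -> genomic 60400
  cpgs <- cpgs_tbl("chr1", c(10300, 60400), c(20, 80))
  prof <- methylation_distance_profile(cpgs, genes, flank = 1000)
  expect_equal(sort(prof$points$distance), c(-400, 300))
  expect_equal(prof$points$methylation[prof$points$distance == 300], 20)
  expect_equal(prof$points$methylation[prof$points$distance == -400], 80)
  # CpGs beyond the flank are dropped
  far <- cpgs_tbl("chr1", 15000, 50)
  expect_equal(nrow(methylation_distance_profile(far, genes)$points), 0L)
})

test_that("the polynomial fit tracks a smooth dip around the TSS", {
  genes <- genes_tbl("chr1", seq(100000, 1000000, by = 100000) ,
                     seq(100000, 1000000, by = 100000) + 20000,
                     strand = "+")
  withr::with_seed(16, {
    offs <- sample(-900:900, 400, replace = TRUE)
    tss <- genes$start[sample.int(nrow(genes), 400, replace = TRUE)]
    meth <- 20 + 50 * (abs(offs) / 900)^2 + rnorm(400, 0, 3)
  })
  cpgs <- cpgs_tbl("chr1", tss + offs, pmin(pmax(meth, 0), 100))
  prof <- methylation_distance_profile(cpgs, genes, flank = 1000)
  expect_gt(nrow(prof$curve), 0)
  centre <- prof$curve$fitted[which.min(abs(prof$curve$distance))]
  edge <- prof$curve$fitted[which.max(prof$curve$distance)]
  expect_lt(centre, edge)  # methylation lowest at the TSS
})
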