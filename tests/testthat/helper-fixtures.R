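# Small in-code fixture builders shared across test files.

peaks_tbl <- function(chrom, start, end, signal = 5,
                      name = sprintf("p%d", seq_along(start))) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = name, score = 0, strand = ".",
    signal_value = rep_len(signal, length(start))
  )
}

genes_tbl <- function(chrom, start, end, strand,
                      gene_id = sprintf("g%d", seq_along(start)),
                      biotype = "protein_coding") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand,
    biotype = rep_len(biotype, length(start))
  )
}

cpgs_tbl <- function(chrom, position, methylation_pct, coverage = 20) {
  tibble::tibble(
    chrom = chrom, position = as.integer(position),
    methylation_pct = methylation_pct,
    coverage = as.integer(rep_len(coverage, length(position)))
  )
}

expr_tbl <- function(gene_id, rpkm, reproducible = TRUE) {
  tibble::tibble(gene_id = gene_id, rpkm = rpkm,
                 reproducible = rep_len(reproducible, length(gene_id)))
}

states_tbl <- function(gene_id, N, H, F, C, mean_methylation = NA_real_) {
  tibble::tibble(gene_id = gene_id, N = N, H = H, F = F, C = C,
                 mean_methylation = rep_len(mean_methylation,
                                            length(gene_id)))
}

random_peaks <- function(n, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(1e6, n)
    peaks_tbl(
      chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
      start = start,
      end = start + sample(100:5000, n, replace = TRUE),
      signal = round(stats::runif(n, 0, 50), 3)
    )
  })
}

# Random observed state table over the full axis alphabet.
random_states <- function(n, seed = 1) {
  withr::with_seed(seed, {
    meth <- stats::runif(n, 0, 100)
    C <- sample(c("l", "h", "f"), n, replace = TRUE)
    meth[C == "f"] <- NA
    meth[C == "l"] <- meth[C == "l"] * 0.299
    meth[C == "h"] <- 30 + meth[C == "h"] * 0.7
    states_tbl(
      gene_id = sprintf("g%04d", seq_len(n)),
      N = sample(c("t", "f"), n, replace = TRUE),
      H = sample(c("t", "f"), n, replace = TRUE),
      F = sample(c("t", "f"), n, replace = TRUE),
      C = C, mean_methylation = meth
    )
  })
}
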