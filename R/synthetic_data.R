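# Synthetic-data generator: every input the pipeline consumes, with
# planted, parameterized structure (a bound gene subset with shifted
# expression; a drug whose sensitivity tracks cistrome-gene
# expression), so all stages are testable with no download.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the statistical structure of the real inputs: a
#' bound fraction of protein-coding genes comparable to a proximal
#' cistrome (~12.5% of genes), ~75% of genes detectably expressed,
#' log-normal RPKM (so the estimated Box-Cox lambda is near 0 and the
#' transformed scale is close to the log scale), log-normal peak
#' lengths averaging a few kb, beta-mixture CpG methylation with
#' negative-binomial coverage, and a 60-line panel with one planted
#' drug whose sensitivity correlates with mean bound-gene expression.
#'
#' @param seed Integer seed; generation is deterministic given it.
#' @param n_genes Number of genes.
#' @param n_chroms Number of chromosomes genes are spread over.
#' @param frac_protein_coding Fraction of genes with biotype
#'   `protein_coding` (the rest are `lincRNA`).
#' @param frac_bound Fraction of genes given a planted proximal factor
#'   peak (the true cistrome); drawn from protein-coding genes.
#' @param expression_shift_delta Log-scale mean shift added to the
#'   expression of bound genes (approximately the transformed-scale
#'   shift, since lambda is near 0).
#' @param frac_on Probability a gene is detectably expressed.
#' @param peak_length_meanlog,peak_length_sdlog Log-normal peak length
#'   parameters.
#' @param peak_signal_meanlog,peak_signal_sdlog Log-normal peak signal
#'   parameters (used as-is for background peaks; planted TSS peaks get
#'   signal `min_planted_signal + lognormal` so the planted cistrome
#'   survives the standard intensity filter).
#' @param min_planted_signal Signal floor for planted peaks.
#' @param n_background_peaks Peaks per track placed away from any
#'   planted structure, drawn from the unclipped distributions (some
#'   fall below the signal filter or above the length filter).
#' @param frac_mark,frac_open Fractions of genes given a histone-mark /
#'   open-chromatin peak near the TSS (independent of binding).
#' @param frac_meth_covered Fraction of genes whose TSS window contains
#'   CpGs.
#' @param n_cpg_per_tss CpGs simulated per covered TSS window.
#' @param frac_low_meth Probability a covered gene draws from the low
#'   beta component.
#' @param meth_alpha_low,meth_beta_low,meth_alpha_high,meth_beta_high
#'   Beta parameters of the low / high methylation components.
#' @param coverage_mean,coverage_dispersion Negative-binomial read
#'   coverage (mu / size).
#' @param n_cell_lines Panel width (60, NCI-60 style).
#' @param n_drugs Number of drugs in the sensitivity matrix.
#' @param planted_drug_effect Correlation strength between the planted
#'   drug's sensitivity and standardized mean bound-gene expression
#'   across lines (0 disables planting).
#' @param cistrome_coexpression Loading of the shared per-line factor in
#'   bound-gene panel expression (gives bound genes correlated
#'   expression across lines, which the planted drug can track).
#' @return A validated list of class `cistra_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 2000,
                             n_chroms = 4,
                             frac_protein_coding = 0.9,
                             frac_bound = 0.125,
                             expression_shift_delta = 0.75,
                             frac_on = 0.748,
                             peak_length_meanlog = log(3000),
                             peak_length_sdlog = 0.8,
                             peak_signal_meanlog = log(4),
                             peak_signal_sdlog = 0.6,
                             min_planted_signal = 2,
                             n_background_peaks = 300,
                             frac_mark = 0.2,
                             frac_open = 0.4,
                             frac_meth_covered = 0.8,
                             n_cpg_per_tss = 8,
                             frac_low_meth = 0.7,
                             meth_alpha_low = 1, meth_beta_low = 9,
                             meth_alpha_high = 6, meth_beta_high = 4,
                             coverage_mean = 30, coverage_dispersion = 5,
                             n_cell_lines = 60,
                             n_drugs = 50,
                             planted_drug_effect = 0.8,
                             cistrome_coexpression = 1) {
  cfg <- as.list(environment())
  fracs <- c(frac_protein_coding, frac_bound, frac_on, frac_mark, frac_open,
             frac_meth_covered, frac_low_meth)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_genes < 1 || n_chroms < 1 || n_cell_lines < 2 || n_drugs < 1) {
    stop("sizes must be positive", call. = FALSE)
  }
  if (frac_bound > 0 && round(frac_bound * n_genes) < 1) {
    stop("infeasible config: frac_bound * n_genes < 1 with planting ",
         "requested", call. = FALSE)
  }
  if (abs(planted_drug_effect) > 1) {
    stop("planted_drug_effect must lie in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "cistra_config")
}

# Place a peak of the given length centered within +/- jitter of pos.
.peak_at <- function(pos, len, jitter = 500) {
  center <- pos + round(runif(length(pos), -jitter, jitter))
  start <- pmax(0L, as.integer(round(center - len / 2)))
  tibble(start = start, end = as.integer(start + round(len)))
}

#' Generate a synthetic dataset
#'
#' Deterministic given `config$seed`.  Bound genes receive a factor
#' peak whose center is uniform within +/-500 bp of the TSS; expression
#' is log-normal with the bound genes' log-mean shifted by
#' `expression_shift_delta`; off genes (probability `1 - frac_on`) have
#' `NA` RPKM; CpG methylation is drawn per gene from a low or high beta
#' component with negative-binomial coverage in two replicates; panel
#' matrices are standard normal with the planted drug's sensitivity row
#' built from the standardized mean bound-gene expression per line.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `cistra_dataset` with elements `genes`,
#'   `factor_peaks`, `mark_peaks`, `open_peaks`, `meth_rep1`,
#'   `meth_rep2`, `expression`, `drug_matrix`, `expr_panel`, `truth`
#'   (list: `bound_genes`, `planted_drug`, `labels` tibble) and
#'   `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "cistra_config"))
  with_seed(config$seed, .generate_dataset_impl(config))
}

.generate_dataset_impl <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% cfg$n_chroms)
  # place genes along each chromosome with generous gaps so TSS windows
  # and metagene flanks never collide
  len <- pmin(pmax(round(rlnorm(n, log(8000), 0.6)), 1500L), 60000L)
  gap <- round(runif(n, 8000, 15000))
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- 10000L + cumsum(c(0L, (len[i] + gap[i])[-length(i)]))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- ifelse(runif(n) < cfg$frac_protein_coding,
                    "protein_coding", "lincRNA")
  genes <- tibble(gene_id = gene_id, chrom = chrom,
                  start = as.integer(start),
                  end = as.integer(start + len),
                  strand = strand, biotype = biotype)
  tss <- ifelse(strand == "+", genes$start, genes$end)

  pc <- which(biotype == "protein_coding")
  n_bound <- round(cfg$frac_bound * n)
  bound_idx <- if (n_bound > 0) sort(sample(pc, min(n_bound, length(pc))))
               else integer(0)
  bound_genes <- gene_id[bound_idx]

  planted_peaks <- function(idx, len_meanlog, len_sdlog, prefix) {
    if (!length(idx)) {
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), name = character(), score = double(),
                    strand = character(), signal_value = double()))
    }
    plen <- pmax(round(rlnorm(length(idx), len_meanlog, len_sdlog)), 200)
    iv <- .peak_at(tss[idx], plen)
    tibble(chrom = chrom[idx], start = iv$start, end = iv$end,
           name = sprintf("%s%05d", prefix, seq_along(idx)),
           score = 0, strand = ".",
           signal_value = cfg$min_planted_signal +
             rlnorm(length(idx), cfg$peak_signal_meanlog,
                    cfg$peak_signal_sdlog))
  }
  background_peaks <- function(n_bg, prefix) {
    if (!n_bg) {
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), name = character(), score = double(),
                    strand = character(), signal_value = double()))
    }
    # heavy-tailed lengths so some exceed the 100 kb filter
    blen <- pmax(round(rlnorm(n_bg, cfg$peak_length_meanlog,
                              cfg$peak_length_sdlog * 1.5)), 200)
    bchrom <- paste0("chr", sample.int(cfg$n_chroms, n_bg, replace = TRUE))
    bstart <- as.integer(round(runif(n_bg, 0, max(genes$end))))
    tibble(chrom = bchrom, start = bstart,
           end = as.integer(bstart + blen),
           name = sprintf("%s%05d", prefix, seq_len(n_bg)),
           score = 0, strand = ".",
           signal_value = rlnorm(n_bg, cfg$peak_signal_meanlog,
                                 cfg$peak_signal_sdlog))
  }
  factor_peaks <- rbind(
    planted_peaks(bound_idx, cfg$peak_length_meanlog, cfg$peak_length_sdlog,
                  "fp"),
    background_peaks(cfg$n_background_peaks, "fb"))
  mark_idx <- which(runif(n) < cfg$frac_mark)
  open_idx <- which(runif(n) < cfg$frac_open)
  mark_peaks <- rbind(
    planted_peaks(mark_idx, log(1500), 0.5, "hp"),
    background_peaks(cfg$n_background_peaks, "hb"))
  open_peaks <- rbind(
    planted_peaks(open_idx, log(800), 0.5, "op"),
    background_peaks(cfg$n_background_peaks, "ob"))

  # methylation: per covered gene a latent low/high component, per CpG a
  # beta-drawn methylation level observed through binomial reads in two
  # replicates
  meth_genes <- which(runif(n) < cfg$frac_meth_covered)
  # shared latent per-CpG methylation; each replicate observes it
  # through its own binomial reads so replicates agree up to sampling
  latent <- lapply(seq_along(meth_genes), function(j) {
    g <- meth_genes[j]
    low <- runif(1) < cfg$frac_low_meth
    m <- if (low) rbeta(cfg$n_cpg_per_tss, cfg$meth_alpha_low,
                        cfg$meth_beta_low)
         else rbeta(cfg$n_cpg_per_tss, cfg$meth_alpha_high,
                    cfg$meth_beta_high)
    pos <- sort(unique(tss[g] + sample(-800:799, cfg$n_cpg_per_tss)))
    list(g = g, pos = pos, m = m[seq_along(pos)])
  })
  observe_rep <- function() {
    out <- lapply(latent, function(lt) {
      cov <- rnbinom(length(lt$pos), mu = cfg$coverage_mean,
                     size = cfg$coverage_dispersion)
      pct <- ifelse(cov > 0,
                    100 * rbinom(length(lt$pos), cov, lt$m) / pmax(cov, 1L),
                    0)
      tibble(chrom = chrom[lt$g], position = as.integer(lt$pos),
             methylation_pct = pct, coverage = as.integer(cov))
    })
    df <- do.call(rbind, out)
    if (is.null(df)) {
      df <- tibble(chrom = character(), position = integer(),
                   methylation_pct = double(), coverage = integer())
    }
    df[order(df$chrom, df$position), ]
  }
  meth_rep1 <- observe_rep()
  meth_rep2 <- observe_rep()

  # expression: off with probability 1 - frac_on; on genes log-normal,
  # bound genes shifted on the log scale
  is_bound <- gene_id %in% bound_genes
  on <- runif(n) < cfg$frac_on
  log_rpkm <- rnorm(n, 0.5 + cfg$expression_shift_delta * is_bound, 1)
  rpkm <- ifelse(on, exp(log_rpkm), NA_real_)
  # a few detected-but-irreproducible records to exercise exclusion
  reproducible <- !(on & runif(n) < 0.02)
  expression <- tibble(gene_id = gene_id, rpkm = rpkm,
                       reproducible = reproducible)

  # panel matrices: bound genes share a per-line latent factor; the
  # planted drug's sensitivity tracks the standardized mean bound-gene
  # expression with the configured correlation strength
  lines <- sprintf("L%02d", seq_len(cfg$n_cell_lines))
  u <- rnorm(cfg$n_cell_lines)
  expr_panel <- matrix(rnorm(n * cfg$n_cell_lines), n,
                       dimnames = list(gene_id, lines))
  if (length(bound_idx) && cfg$cistrome_coexpression > 0) {
    a <- cfg$cistrome_coexpression
    expr_panel[bound_idx, ] <-
      (rep(1, length(bound_idx)) %o% (a * u) +
         matrix(rnorm(length(bound_idx) * cfg$n_cell_lines),
                length(bound_idx))) / sqrt(1 + a^2)
  }
  expr_panel <- expr_panel - rowMeans(expr_panel)
  drug_ids <- sprintf("D%03d", seq_len(cfg$n_drugs))
  drug_matrix <- matrix(rnorm(cfg$n_drugs * cfg$n_cell_lines), cfg$n_drugs,
                        dimnames = list(drug_ids, lines))
  planted_drug <- NA_character_
  if (length(bound_idx) && cfg$planted_drug_effect != 0) {
    planted_drug <- sample(drug_ids, 1)
    s <- colMeans(expr_panel[bound_idx, , drop = FALSE])
    s <- (s - mean(s)) / sd(s)
    eff <- cfg$planted_drug_effect
    drug_matrix[planted_drug, ] <- eff * s +
      sqrt(1 - eff^2) * rnorm(cfg$n_cell_lines)
  }
  drug_matrix <- drug_matrix - rowMeans(drug_matrix)

  structure(list(
    genes = genes,
    factor_peaks = factor_peaks,
    mark_peaks = mark_peaks,
    open_peaks = open_peaks,
    meth_rep1 = meth_rep1,
    meth_rep2 = meth_rep2,
    expression = expression,
    drug_matrix = drug_matrix,
    expr_panel = expr_panel,
    truth = list(
      bound_genes = bound_genes,
      planted_drug = planted_drug,
      labels = tibble(gene_id = gene_id, bound = is_bound)
    ),
    config = cfg
  ), class = "cistra_dataset")
}

#' Collapse peaks into a non-overlapping signal track
#'
#' Where peaks overlap, their signal values add; the result is a
#' sorted, non-overlapping bedGraph-style track (zero-signal runs are
#' omitted).
#'
#' @param peaks Peak tibble.
#' @return A signal track tibble (`chrom`, `start`, `end`, `value`).
#' @export
peaks_to_track <- function(peaks) {
  if (!nrow(peaks)) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), value = double()))
  }
  gr <- .gr(peaks$chrom, peaks$start, peaks$end)
  cov <- coverage(gr, weight = peaks$signal_value)
  out <- lapply(names(cov), function(ch) {
    rl <- cov[[ch]]
    ends <- cumsum(runLength(rl))
    starts <- ends - runLength(rl)
    vals <- runValue(rl)
    keep <- vals != 0
    tibble(chrom = ch, start = as.integer(starts[keep]),
           end = as.integer(ends[keep]), value = as.numeric(vals[keep]))
  })
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), ]
}

.dataset_files <- c(
  genes = "genes.tsv",
  factor_peaks = "factor_peaks.broadPeak",
  mark_peaks = "mark_peaks.broadPeak",
  open_peaks = "open_peaks.broadPeak",
  meth_rep1 = "methylation_rep1.tsv",
  meth_rep2 = "methylation_rep2.tsv",
  expression = "expression.tsv",
  drug_matrix = "drug_matrix.tsv",
  expr_panel = "expr_panel.tsv",
  factor_track = "factor_track.bedgraph",
  truth_bound = "truth_bound_genes.txt",
  truth_labels = "truth_labels.tsv"
)

#' Write a synthetic dataset to a directory
#'
#' Emits every format the pipeline reads, plus truth labels and a
#' manifest of files with row counts.
#'
#' @param dataset A `cistra_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (`file`, `rows`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(dir, .dataset_files[[name]])
  write_gene_models(dataset$genes, fp("genes"))
  write_peaks(dataset$factor_peaks, fp("factor_peaks"))
  write_peaks(dataset$mark_peaks, fp("mark_peaks"))
  write_peaks(dataset$open_peaks, fp("open_peaks"))
  write_methylation(dataset$meth_rep1, fp("meth_rep1"))
  write_methylation(dataset$meth_rep2, fp("meth_rep2"))
  write_expression(dataset$expression, fp("expression"))
  write_panel_matrix(dataset$drug_matrix, fp("drug_matrix"))
  write_panel_matrix(dataset$expr_panel, fp("expr_panel"))
  write_signal_track(peaks_to_track(dataset$factor_peaks),
                     fp("factor_track"))
  write_gene_list(dataset$truth$bound_genes, fp("truth_bound"))
  write.table(dataset$truth$labels, fp("truth_labels"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rows <- c(
    nrow(dataset$genes), nrow(dataset$factor_peaks),
    nrow(dataset$mark_peaks), nrow(dataset$open_peaks),
    nrow(dataset$meth_rep1), nrow(dataset$meth_rep2),
    nrow(dataset$expression), nrow(dataset$drug_matrix),
    nrow(dataset$expr_panel), nrow(peaks_to_track(dataset$factor_peaks)),
    length(dataset$truth$bound_genes), nrow(dataset$truth$labels)
  )
  manifest <- tibble(file = unname(.dataset_files[c(
    "genes", "factor_peaks", "mark_peaks", "open_peaks", "meth_rep1",
    "meth_rep2", "expression", "drug_matrix", "expr_panel", "factor_track",
    "truth_bound", "truth_labels")]), rows = rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a written synthetic dataset back from disk
#'
#' Inverse of [write_dataset()] (the generator config is not
#' persisted; the returned object carries `config = NULL`).
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `cistra_dataset`.
#' @export
read_dataset <- function(dir) {
  fp <- function(name) file.path(dir, .dataset_files[[name]])
  labels <- utils::read.delim(fp("truth_labels"), stringsAsFactors = FALSE)
  structure(list(
    genes = read_gene_models(fp("genes")),
    factor_peaks = read_peaks(fp("factor_peaks"), "broadPeak"),
    mark_peaks = read_peaks(fp("mark_peaks"), "broadPeak"),
    open_peaks = read_peaks(fp("open_peaks"), "broadPeak"),
    meth_rep1 = read_methylation(fp("meth_rep1")),
    meth_rep2 = read_methylation(fp("meth_rep2")),
    expression = read_expression(fp("expression")),
    drug_matrix = read_panel_matrix(fp("drug_matrix")),
    expr_panel = read_panel_matrix(fp("expr_panel")),
    truth = list(
      bound_genes = read_gene_list(fp("truth_bound")),
      planted_drug = NA_character_,
      labels = tibble(gene_id = labels$gene_id,
                      bound = as.logical(labels$bound))
    ),
    config = NULL
  ), class = "cistra_dataset")
}
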