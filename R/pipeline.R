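# End-to-end orchestration: annotate -> on/off + bootstrap per catalog
# query -> metagene bin correlation -> drug enrichment, with a
# reproducibility manifest.

#' Pipeline parameters
#'
#' All stage thresholds with their standard defaults: 1 kb TSS flank,
#' 25% peak-fraction overlap, peak filter (signal >= 2, length <=
#' 100 kb), >= 10 reads in both methylation replicates, 30% methylation
#' cut, 100,000 bootstrap resamples, the 40/100/4100 bin schema, gene
#' FDR 0.1 and enrichment FDR 0.01.
#'
#' @param flank TSS window half-width (bp).
#' @param min_overlap_frac Peak-fraction overlap threshold.
#' @param min_signal,max_peak_length Peak filter thresholds.
#' @param min_reads Methylation replicate coverage threshold.
#' @param meth_cut Low/high methylation cut (%).
#' @param bootstrap_B Bootstrap resamples per subset.
#' @param min_subset_n Smallest subset size tested by bootstrap.
#' @param schema Metagene [bin_schema()].
#' @param gene_fdr Drug-gene correlation FDR.
#' @param enrich_fdr Cistrome enrichment FDR.
#' @param seed Master seed for all stochastic stages.
#' @return A named list of class `cistra_params`.
#' @export
pipeline_params <- function(flank = 1000, min_overlap_frac = 0.25,
                            min_signal = 2, max_peak_length = 100000,
                            min_reads = 10, meth_cut = 30,
                            bootstrap_B = 100000, min_subset_n = 2,
                            schema = bin_schema(), gene_fdr = 0.1,
                            enrich_fdr = 0.01, seed = 1) {
  p <- as.list(environment())
  pos <- c(flank, min_overlap_frac, min_signal, max_peak_length, min_reads,
           meth_cut, bootstrap_B, min_subset_n, gene_fdr, enrich_fdr)
  if (any(pos <= 0)) stop("every threshold must be positive", call. = FALSE)
  structure(p, class = "cistra_params")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full integrative pipeline
#'
#' Executes, on an in-memory dataset (see [generate_dataset()] /
#' [read_dataset()]): peak filtering, methylation replicate merging,
#' state annotation restricted to protein-coding genes, on/off calling
#' and Box-Cox transformation, a bootstrap expression test plus an
#' on/off hypergeometric test for every non-empty sub-cistrome in the
#' 36-query lattice, the 81-bin binding-signal/expression correlation,
#' and drug-sensitivity cistrome enrichment.  Any stage error aborts
#' with the stage name.  All statistical outputs are pure functions of
#' (dataset, params), so a rerun with the same inputs reproduces them.
#'
#' @param dataset A `cistra_dataset` (or compatible named list).
#' @param params A [pipeline_params()].
#' @return A list with `states`, `catalog`, `subset_results` (one row
#'   per tested sub-cistrome: query, n, n_on, observed means on both
#'   scales, null mean and CI, bootstrap and on/off p-values), `lambda`,
#'   `bin_correlation`, `drug_enrichment`, and `manifest` (per-stage row
#'   counts and timings).
#' @export
run_pipeline <- function(dataset, params = pipeline_params()) {
  stopifnot(inherits(params, "cistra_params"))
  manifest <- list()
  tick <- function(name, rows, t0) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = name, rows = rows,
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }

  t0 <- as.numeric(Sys.time())
  factor_peaks <- .stage("filter_peaks", filter_peaks(
    dataset$factor_peaks, max_length = params$max_peak_length,
    min_signal = params$min_signal))
  tick("filter_peaks", nrow(factor_peaks), t0)

  t0 <- as.numeric(Sys.time())
  cpgs <- .stage("merge_methylation", {
    if (is.null(dataset$meth_rep1) || is.null(dataset$meth_rep2)) {
      stop("methylation replicates missing")
    }
    merge_methylation_replicates(dataset$meth_rep1, dataset$meth_rep2,
                                 min_reads = params$min_reads)
  })
  tick("merge_methylation", nrow(cpgs), t0)

  t0 <- as.numeric(Sys.time())
  states <- .stage("annotate", {
    genes <- dataset$genes[dataset$genes$biotype == "protein_coding", ]
    annotate_states(genes, factor_peaks, dataset$mark_peaks,
                    dataset$open_peaks, cpgs, flank = params$flank,
                    min_overlap_frac = params$min_overlap_frac,
                    meth_cut = params$meth_cut)
  })
  tick("annotate", nrow(states), t0)

  t0 <- as.numeric(Sys.time())
  tx <- .stage("expression", {
    expr <- dataset$expression[
      dataset$expression$gene_id %in% states$gene_id, ]
    transform_expression(expr)
  })
  catalog <- .stage("catalog", enumerate_subsets(states, fixed_N = "t"))
  tick("catalog", nrow(catalog), t0)

  t0 <- as.numeric(Sys.time())
  subset_results <- .stage("bootstrap", {
    background <- states$gene_id
    on_set <- tx$on
    universe <- intersect(states$gene_id, c(tx$on, tx$off))
    rows <- list()
    for (i in seq_len(nrow(catalog))) {
      genes_i <- catalog$gene_ids[[i]]
      testable <- intersect(genes_i, names(tx$values))
      if (length(testable) < params$min_subset_n) next
      bt <- bootstrap_mean_test(testable, background, tx$values,
                                B = params$bootstrap_B,
                                seed = params$seed + i)
      oo <- onoff_hypergeometric(genes_i, on_set, universe)
      rows[[length(rows) + 1]] <- tibble(
        query = catalog$query[i],
        n = length(genes_i),
        n_on = oo$subset_on,
        observed_mean = bt$observed_mean,
        observed_mean_rpkm = mean(tx$rpkm[testable]),
        null_mean = bt$null_mean,
        ci_low = bt$ci[1], ci_high = bt$ci[2],
        p_upper = bt$p_upper, p_lower = bt$p_lower,
        p_two_sided = bt$p_two_sided,
        onoff_p = oo$p)
    }
    do.call(rbind, rows)
  })
  tick("bootstrap", nrow(subset_results), t0)

  t0 <- as.numeric(Sys.time())
  bin_correlation <- .stage("bins", {
    track <- peaks_to_track(factor_peaks)
    genes <- dataset$genes[dataset$genes$biotype == "protein_coding", ]
    bm <- bin_matrix(genes, track, params$schema)
    if (nrow(bm$matrix) >= 3) {
      per_bin_correlation(bm$matrix, log(tx$rpkm))
    } else {
      tibble(bin = integer(), r = double(), p = double(),
             mean_signal = double())
    }
  })
  tick("bins", nrow(bin_correlation), t0)

  t0 <- as.numeric(Sys.time())
  drug_enrichment <- .stage("drugmatrix", {
    if (is.null(dataset$drug_matrix) || is.null(dataset$expr_panel)) {
      tibble()
    } else {
      cors <- correlate_drug_genes(dataset$drug_matrix, dataset$expr_panel)
      sets <- build_drug_gene_sets(cors, fdr = params$gene_fdr)
      cistrome <- intersect(select_subset(states, subset_query(N = "t")),
                            rownames(dataset$expr_panel))
      rank_cistrome_enrichment(sets, cistrome,
                               universe = rownames(dataset$expr_panel),
                               fdr = params$enrich_fdr)
    }
  })
  tick("drugmatrix", nrow(drug_enrichment), t0)

  list(
    states = states,
    catalog = catalog,
    subset_results = subset_results,
    lambda = tx$lambda,
    bin_correlation = bin_correlation,
    drug_enrichment = drug_enrichment,
    manifest = do.call(rbind, manifest)
  )
}
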