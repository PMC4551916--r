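# Expression transformation, on/off calling and subset tests against
# bootstrap resampling nulls and hypergeometric on/off expectations.

#' Call on and off genes
#'
#' A gene is *on* when it passed reproducibility (IDR) filtering and has
#' an RPKM value; *off* when it passed filtering but has no RPKM value
#' (reproducibly undetected).  Records with an RPKM value but
#' `reproducible = FALSE` fall outside the analysis universe and are
#' returned separately; on/off is an exhaustive partition of the
#' remaining records.
#'
#' @param expression Expression tibble (see [read_expression()]).
#' @return A list with character vectors `on`, `off` and `excluded`.
#' @export
call_on_off <- function(expression) {
  on <- expression$reproducible & !is.na(expression$rpkm)
  off <- is.na(expression$rpkm)
  list(on = expression$gene_id[on],
       off = expression$gene_id[off],
       excluded = expression$gene_id[!on & !off])
}

.boxcox <- function(x, lambda) {
  if (abs(lambda) < .Machine$double.eps^0.5) log(x) else (x^lambda - 1) / lambda
}

# Profile log-likelihood of the Box-Cox model at lambda (normal errors,
# MLE variance plugged in; the Jacobian term is (lambda-1) * sum(log x)).
.boxcox_loglik <- function(x, lambda, sum_log_x) {
  y <- .boxcox(x, lambda)
  n <- length(x)
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum_log_x
}

#' Box-Cox transform with profile-likelihood lambda
#'
#' Transforms strictly positive values by `y = (x^lambda - 1) / lambda`
#' (`y = log(x)` at `lambda = 0`).  When `lambda` is not supplied it is
#' chosen by maximizing the profile log-likelihood over a grid on
#' \[-2, 2\] with step 0.01; likelihood ties are broken toward 0.
#'
#' @param values Strictly positive numeric vector (names preserved).
#' @param lambda Optional fixed exponent; skip estimation.
#' @param grid Candidate lambdas searched when `lambda` is `NULL`.
#' @return A list with `values` (transformed, names preserved) and
#'   `lambda`.
#' @export
boxcox_transform <- function(values, lambda = NULL,
                             grid = seq(-2, 2, by = 0.01)) {
  if (!length(values)) stop("no values to transform", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox transform requires strictly positive finite values",
         call. = FALSE)
  }
  if (is.null(lambda)) {
    slx <- sum(log(values))
    ll <- vapply(grid, function(l) .boxcox_loglik(values, l, slx), 0)
    best <- which(ll >= max(ll) - 1e-9)
    lambda <- grid[best[which.min(abs(grid[best]))]]
  }
  out <- .boxcox(values, lambda)
  names(out) <- names(values)
  list(values = out, lambda = lambda)
}

#' Transform an expression table for subset testing
#'
#' Calls on/off genes, then Box-Cox transforms the RPKM values of the
#' on genes (zero RPKMs cannot be power-transformed and are dropped
#' with a message).
#'
#' @param expression Expression tibble.
#' @inheritParams boxcox_transform
#' @return A list with `values` (named transformed vector over on
#'   genes), `rpkm` (named raw vector over the same genes), `lambda`,
#'   `n_on`, `n_off`, `on`, `off`.
#' @export
transform_expression <- function(expression, lambda = NULL) {
  calls <- call_on_off(expression)
  idx <- match(calls$on, expression$gene_id)
  rpkm <- setNames(expression$rpkm[idx], calls$on)
  nonpos <- rpkm <= 0
  if (any(nonpos)) {
    message(sum(nonpos), " on gene(s) with non-positive RPKM dropped ",
            "from the transformed scale")
    rpkm <- rpkm[!nonpos]
  }
  bc <- boxcox_transform(rpkm, lambda = lambda)
  list(values = bc$values, rpkm = rpkm, lambda = bc$lambda,
       n_on = length(calls$on), n_off = length(calls$off),
       on = calls$on, off = calls$off)
}

#' Bootstrap resampling test for subset mean expression
#'
#' Compares the observed mean (transformed) expression of a gene subset
#' to an empirical null built from `B` random gene sets of the same
#' size drawn from the background.  Each resampled set is drawn without
#' replacement within a draw by default (a random same-size gene
#' signature); draws are independent across `B`.  Empirical p-values
#' use the add-one rule, `p_upper = (1 + #\{null >= observed\}) /
#' (B + 1)`, so the smallest attainable p is `1/(B + 1)` and 0 is never
#' reported.
#'
#' @param subset_genes Character vector; must be a subset of
#'   `background_genes` after restriction to genes with values.
#' @param background_genes Character vector of background gene ids.
#' @param values Named numeric vector of (transformed) expression.
#' @param B Number of resamples.
#' @param seed Integer seed; the test is bit-identical given the seed.
#' @param replace Sample gene ids with replacement within each draw
#'   (classical bootstrap) instead of without.
#' @param keep_null Also return the full vector of null means.
#' @return An object of class `cistra_bootstrap`: a list with
#'   `observed_mean`, `n_genes`, `B`, `null_mean`, `ci` (2.5 and 97.5
#'   null percentiles), `p_upper`, `p_lower`, `p_two_sided`, `seed`,
#'   and optionally `null_means`.
#' @export
bootstrap_mean_test <- function(subset_genes, background_genes, values,
                                B = 100000, seed = 1, replace = FALSE,
                                keep_null = FALSE) {
  subset_genes <- intersect(unique(subset_genes), names(values))
  background_genes <- intersect(unique(background_genes), names(values))
  if (!length(subset_genes)) {
    stop("subset is empty after restricting to genes with values",
         call. = FALSE)
  }
  extra <- setdiff(subset_genes, background_genes)
  if (length(extra)) {
    stop(sprintf("subset not contained in background (%d gene(s) outside)",
                 length(extra)), call. = FALSE)
  }
  bg <- unname(values[background_genes])
  m <- length(subset_genes)
  nb <- length(bg)
  observed <- mean(values[subset_genes])
  null_means <- numeric(B)
  with_seed(seed, {
    if (replace) {
      for (b in seq_len(B)) {
        null_means[b] <- sum(bg[sample.int(nb, m, replace = TRUE)]) / m
      }
    } else {
      for (b in seq_len(B)) {
        null_means[b] <- sum(bg[sample.int(nb, m)]) / m
      }
    }
  })
  # ties within floating-point noise of the observed mean count as ties
  # (a subset equal to its background must give p = 1, not a spurious
  # tail from summation order)
  eps <- 1e-12 * max(1, abs(observed))
  p_upper <- (1 + sum(null_means >= observed - eps)) / (B + 1)
  p_lower <- (1 + sum(null_means <= observed + eps)) / (B + 1)
  res <- list(
    observed_mean = observed,
    n_genes = m,
    B = B,
    null_mean = mean(null_means),
    ci = quantile(null_means, c(0.025, 0.975), names = FALSE),
    p_upper = p_upper,
    p_lower = p_lower,
    p_two_sided = min(1, 2 * min(p_upper, p_lower)),
    seed = seed
  )
  if (keep_null) res$null_means <- null_means
  structure(res, class = "cistra_bootstrap")
}

#' @export
print.cistra_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap mean test: %d genes, B = %d\n  observed %.4f vs null %.4f [%.4f, %.4f]\n  p_upper %.3g  p_lower %.3g  p_two_sided %.3g\n",
    x$n_genes, x$B, x$observed_mean, x$null_mean, x$ci[1], x$ci[2],
    x$p_upper, x$p_lower, x$p_two_sided))
  invisible(x)
}

#' Matched background for a sub-cistrome query
#'
#' Genes sharing the query's H/F/C state axes but *lacking* the factor
#' (N = f): the parsimonious background for asking what the factor adds
#' on top of a given chromatin context.
#'
#' @param states State tibble from [annotate_states()].
#' @param query A `cistra_query`.
#' @return Character vector of background gene ids.
#' @export
matched_background <- function(states, query) {
  select_subset(states, subset_query("f", query[["H"]], query[["F"]],
                                     query[["C"]]))
}

#' Hypergeometric test of a subset's on/off composition
#'
#' Upper-tail probability of observing at least the subset's number of
#' on genes in a draw of the subset's size from the universe.
#'
#' @param subset Character vector of gene ids.
#' @param on_set Character vector of on genes.
#' @param universe Character vector of all considered genes.
#' @return A one-row tibble with `subset_on`, `subset_size`,
#'   `background_on`, `background_size`, `p`.
#' @export
onoff_hypergeometric <- function(subset, on_set, universe) {
  universe <- unique(universe)
  subset <- intersect(unique(subset), universe)
  on_set <- intersect(unique(on_set), universe)
  k <- length(intersect(subset, on_set))
  tibble(
    subset_on = k,
    subset_size = length(subset),
    background_on = length(on_set),
    background_size = length(universe),
    p = hypergeom_tail(length(universe), length(on_set), length(subset), k)
  )
}
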