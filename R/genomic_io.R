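# Readers and writers for every external format the pipeline touches.
# One convention throughout: coordinates are 0-based half-open, so an
# interval of length L always satisfies end - start == L.  Chromosome
# names are matched by exact string equality (no "chr" aliasing).

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

# Split a text file into whitespace-delimited fields, skipping comment /
# track / browser lines.  Returns list(fields = list of chr vectors,
# lineno = original line numbers).
.read_fields <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  list(
    fields = strsplit(lines[keep], "[ \t]+"),
    lineno = which(keep)
  )
}

.as_coord <- function(x, path, lineno, what) {
  n <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(n) | n != floor(n))
  if (length(bad)) {
    .parse_error(path, lineno[bad[1]],
                 sprintf("non-integer %s '%s'", what, x[bad[1]]))
  }
  as.integer(n)
}

.check_intervals <- function(start, end, path, lineno) {
  bad <- which(start < 0L)
  if (length(bad)) .parse_error(path, lineno[bad[1]], "negative start")
  bad <- which(end <= start)
  if (length(bad)) .parse_error(path, lineno[bad[1]], "start >= end")
  invisible(NULL)
}

#' Read peak calls
#'
#' Reads UCSC-style peak files into a peak table.  The `signal_value`
#' column is taken from the dialect's signal column: column 7
#' (signalValue) for broadPeak/narrowPeak, column 5 (score) for BED6.
#'
#' @param path Path to the peak file.
#' @param dialect One of `"broadPeak"` (9 columns), `"narrowPeak"`
#'   (10 columns) or `"bed6"` (6 columns).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`, `signal_value`.
#' @seealso [write_peaks()], [filter_peaks()]
#' @export
read_peaks <- function(path, dialect = c("broadPeak", "narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  ncol_needed <- switch(dialect, broadPeak = 9L, narrowPeak = 10L, bed6 = 6L)
  fx <- .read_fields(path)
  nf <- lengths(fx$fields)
  bad <- which(nf != ncol_needed)
  if (length(bad)) {
    .parse_error(path, fx$lineno[bad[1]],
                 sprintf("expected %d columns for %s, found %d",
                         ncol_needed, dialect, nf[bad[1]]))
  }
  if (!length(fx$fields)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character(),
                  signal_value = double()))
  }
  col <- function(i) vapply(fx$fields, `[[`, character(1), i)
  start <- .as_coord(col(2), path, fx$lineno, "start")
  end <- .as_coord(col(3), path, fx$lineno, "end")
  .check_intervals(start, end, path, fx$lineno)
  sig_col <- if (dialect == "bed6") 5L else 7L
  signal <- suppressWarnings(as.numeric(col(sig_col)))
  bad <- which(is.na(signal) | signal < 0)
  if (length(bad)) {
    .parse_error(path, fx$lineno[bad[1]], "signal value missing or negative")
  }
  score <- suppressWarnings(as.numeric(col(5)))
  score[is.na(score)] <- 0
  tibble(
    chrom = col(1), start = start, end = end, name = col(4),
    score = score, strand = col(6), signal_value = signal
  )
}

#' Write peak calls
#'
#' Inverse of [read_peaks()]; unused broadPeak/narrowPeak statistics
#' columns are written as -1.
#'
#' @param peaks Peak tibble as returned by [read_peaks()].
#' @inheritParams read_peaks
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("broadPeak", "narrowPeak", "bed6")) {
  dialect <- match.arg(dialect)
  df <- switch(dialect,
    broadPeak = data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                           peaks$score, peaks$strand, peaks$signal_value,
                           -1, -1),
    narrowPeak = data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                            peaks$score, peaks$strand, peaks$signal_value,
                            -1, -1, -1),
    bed6 = data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                      peaks$signal_value, peaks$strand)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Tab-separated with a header line: `chrom`, `start`, `end`, `strand`,
#' `gene_id`, `biotype`.  Strand must be `+` or `-`; `gene_id` must be
#' unique.  The biotype column is preserved verbatim (filtering to, say,
#' protein-coding genes happens downstream).
#'
#' @param path Path to the gene table.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "biotype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop(sprintf("%s: duplicate gene_id '%s'", path,
                 df$gene_id[duplicated(df$gene_id)][1]), call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("%s: unknown strand '%s' for gene '%s'", path,
                 df$strand[bad[1]], df$gene_id[bad[1]]), call. = FALSE)
  }
  if (any(df$end <= df$start)) {
    stop(sprintf("%s: gene with start >= end", path), call. = FALSE)
  }
  tibble(gene_id = as.character(df$gene_id), chrom = as.character(df$chrom),
         start = as.integer(df$start), end = as.integer(df$end),
         strand = df$strand, biotype = as.character(df$biotype))
}

#' @rdname read_gene_models
#' @param genes Gene model tibble.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                   strand = genes$strand, gene_id = genes$gene_id,
                   biotype = genes$biotype)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CpG methylation calls
#'
#' bedGraph-like, no header: `chrom`, `position`, `position + 1`,
#' methylation percentage in \[0, 100\], read coverage.  Output is
#' sorted by (chrom, position).
#'
#' @param path Path to the methylation file.
#' @return A tibble with columns `chrom`, `position` (0-based),
#'   `methylation_pct`, `coverage`.
#' @export
read_methylation <- function(path) {
  fx <- .read_fields(path)
  nf <- lengths(fx$fields)
  bad <- which(nf != 5L)
  if (length(bad)) {
    .parse_error(path, fx$lineno[bad[1]],
                 sprintf("expected 5 columns, found %d", nf[bad[1]]))
  }
  if (!length(fx$fields)) {
    return(tibble(chrom = character(), position = integer(),
                  methylation_pct = double(), coverage = integer()))
  }
  col <- function(i) vapply(fx$fields, `[[`, character(1), i)
  pos <- .as_coord(col(2), path, fx$lineno, "position")
  meth <- suppressWarnings(as.numeric(col(4)))
  bad <- which(is.na(meth) | meth < 0 | meth > 100)
  if (length(bad)) {
    .parse_error(path, fx$lineno[bad[1]],
                 sprintf("methylation '%s' outside [0, 100]", col(4)[bad[1]]))
  }
  cov <- .as_coord(col(5), path, fx$lineno, "coverage")
  if (any(cov < 0L)) .parse_error(path, fx$lineno[which(cov < 0L)[1]],
                                  "negative coverage")
  out <- tibble(chrom = col(1), position = pos,
                methylation_pct = meth, coverage = cov)
  out[order(out$chrom, out$position), ]
}

#' @rdname read_methylation
#' @param cpgs CpG tibble.
#' @export
write_methylation <- function(cpgs, path) {
  df <- data.frame(cpgs$chrom, cpgs$position, cpgs$position + 1L,
                   cpgs$methylation_pct, cpgs$coverage)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene expression records
#'
#' Tab-separated with header columns `gene_id`, `rpkm`, `reproducible`.
#' `rpkm` may be `NA` (the gene was reproducibly undetected and is
#' callable only as off); `reproducible` records whether the gene passed
#' reproducibility (IDR) filtering.
#'
#' @param path Path to the expression table.
#' @return A tibble with columns `gene_id`, `rpkm` (double, `NA`
#'   allowed), `reproducible` (logical).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gene_id", "rpkm", "reproducible")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rpkm <- suppressWarnings(as.numeric(df$rpkm))
  # read.delim already maps literal "NA" to NA; only other non-numeric
  # strings are parse errors
  bad <- which(is.na(rpkm) & !is.na(df$rpkm) & toupper(df$rpkm) != "NA")
  if (length(bad)) {
    stop(sprintf("%s: non-numeric rpkm '%s' for gene '%s'", path,
                 df$rpkm[bad[1]], df$gene_id[bad[1]]), call. = FALSE)
  }
  repro <- toupper(df$reproducible) %in% c("TRUE", "T", "1", "YES")
  tibble(gene_id = df$gene_id, rpkm = rpkm, reproducible = repro)
}

#' @rdname read_expression
#' @param expression Expression tibble.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = expression$gene_id,
                   rpkm = ifelse(is.na(expression$rpkm), "NA",
                                 format(expression$rpkm, digits = 15,
                                        scientific = FALSE, trim = TRUE)),
                   reproducible = ifelse(expression$reproducible,
                                         "true", "false"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a panel matrix (drugs x lines or genes x lines)
#'
#' Tab-separated with a header of cell-line names; the first column
#' holds row identifiers (drug or gene ids).  Values are Z-scores;
#' `NA` is allowed.
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with row and column names.
#' @export
read_panel_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) {
    stop(sprintf("%s: panel matrix needs an id column plus >=1 cell line",
                 path), call. = FALSE)
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate row id '%s'", path,
                 ids[duplicated(ids)][1]), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & toupper(vals) != "NA")
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value '%s'", path, vals[bad[1]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  num
}

#' @rdname read_panel_matrix
#' @param mat Numeric matrix with row/column names.
#' @export
write_panel_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One id per line; duplicates are dropped (first occurrence kept).
#'
#' @param path Path to the list.
#' @return A character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' @rdname read_gene_list
#' @param ids Character vector of gene ids.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(unique(as.character(ids)), path)
  invisible(path)
}

#' Read a signal track (bedGraph)
#'
#' Four columns, no header: `chrom`, `start`, `end`, `value`.  Intervals
#' must be non-overlapping within each chromosome; output is sorted.
#'
#' @param path Path to the bedGraph file.
#' @return A tibble with columns `chrom`, `start`, `end`, `value`.
#' @export
read_signal_track <- function(path) {
  fx <- .read_fields(path)
  nf <- lengths(fx$fields)
  bad <- which(nf != 4L)
  if (length(bad)) {
    .parse_error(path, fx$lineno[bad[1]],
                 sprintf("expected 4 columns, found %d", nf[bad[1]]))
  }
  if (!length(fx$fields)) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), value = double()))
  }
  col <- function(i) vapply(fx$fields, `[[`, character(1), i)
  start <- .as_coord(col(2), path, fx$lineno, "start")
  end <- .as_coord(col(3), path, fx$lineno, "end")
  .check_intervals(start, end, path, fx$lineno)
  value <- suppressWarnings(as.numeric(col(4)))
  bad <- which(is.na(value))
  if (length(bad)) .parse_error(path, fx$lineno[bad[1]], "non-numeric value")
  out <- tibble(chrom = col(1), start = start, end = end, value = value)
  out <- out[order(out$chrom, out$start), ]
  ovl <- which(out$chrom[-1] == out$chrom[-nrow(out)] &
                 out$start[-1] < out$end[-nrow(out)])
  if (length(ovl)) {
    stop(sprintf("%s: overlapping track intervals on %s near position %d",
                 path, out$chrom[ovl[1] + 1], out$start[ovl[1] + 1]),
         call. = FALSE)
  }
  out
}

#' @rdname read_signal_track
#' @param track Signal track tibble.
#' @export
write_signal_track <- function(track, path) {
  df <- data.frame(track$chrom, track$start, track$end,
                   format(track$value, digits = 15, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin interaction pairs
#'
#' Six columns, no header: the two anchors of each interaction as
#' `chrom_a start_a end_a chrom_b start_b end_b`.
#'
#' @param path Path to the interaction file.
#' @return A tibble with the six anchor columns.
#' @export
read_interactions <- function(path) {
  fx <- .read_fields(path)
  nf <- lengths(fx$fields)
  bad <- which(nf != 6L)
  if (length(bad)) {
    .parse_error(path, fx$lineno[bad[1]],
                 sprintf("expected 6 columns, found %d", nf[bad[1]]))
  }
  if (!length(fx$fields)) {
    return(tibble(chrom_a = character(), start_a = integer(),
                  end_a = integer(), chrom_b = character(),
                  start_b = integer(), end_b = integer()))
  }
  col <- function(i) vapply(fx$fields, `[[`, character(1), i)
  sa <- .as_coord(col(2), path, fx$lineno, "start")
  ea <- .as_coord(col(3), path, fx$lineno, "end")
  sb <- .as_coord(col(5), path, fx$lineno, "start")
  eb <- .as_coord(col(6), path, fx$lineno, "end")
  .check_intervals(sa, ea, path, fx$lineno)
  .check_intervals(sb, eb, path, fx$lineno)
  tibble(chrom_a = col(1), start_a = sa, end_a = ea,
         chrom_b = col(4), start_b = sb, end_b = eb)
}

# GRanges from 0-based half-open columns (GRanges is 1-based closed).
.gr <- function(chrom, start, end) {
  GRanges(chrom, IRanges(start + 1L, end))
}

# findOverlaps without the seqlevel-mismatch warning: inputs with
# chromosomes private to one side are a legitimate situation here
# (check_shared_chromosomes is the user-facing diagnostic).
.fo <- function(query, subject) {
  suppressWarnings(findOverlaps(query, subject))
}

#' Warn when two inputs disagree on chromosome names
#'
#' Chromosome matching everywhere in the package is exact string
#' equality; this helper surfaces naming mismatches (e.g. "chr1" vs
#' "1") between inputs.
#'
#' @param a,b Character vectors of chromosome names (any length).
#' @param what Label used in the warning.
#' @return Invisibly, the character vector of unshared names.
#' @export
check_shared_chromosomes <- function(a, b, what = "inputs") {
  ua <- unique(a)
  ub <- unique(b)
  unshared <- c(setdiff(ua, ub), setdiff(ub, ua))
  if (length(unshared) && length(ua) && length(ub)) {
    warning(sprintf("%s do not share chromosomes: %s", what,
                    paste(unshared, collapse = ", ")), call. = FALSE)
  }
  invisible(unshared)
}
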