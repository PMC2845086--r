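#' Average replicate samples
#'
#' Combines samples of the same type into one column holding the per-gene
#' arithmetic mean on the current scale, the way replicate hybridizations of
#' a tissue panel are averaged into one profile per tissue.
#'
#' @param x An \code{\link{expr_matrix}}.
#' @param replicate_map Named character vector: sample id -> aggregate label.
#'   Every sample of \code{x} must be mapped.
#' @return An \code{expr_matrix} with one column per aggregate label, in
#'   first-appearance order of the labels.
#' @export
aggregate_samples <- function(x, replicate_map) {
  missing_samples <- setdiff(colnames(x), names(replicate_map))
  if (length(missing_samples)) {
    stop(sprintf("unmapped sample: '%s'", missing_samples[1L]))
  }
  labels <- replicate_map[colnames(x)]
  out_labels <- unique(unname(labels))
  agg <- vapply(out_labels, function(lab) {
    cols <- which(labels == lab)
    if (!length(cols)) stop(sprintf("empty aggregate group '%s'", lab))
    rowMeans(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  colnames(agg) <- out_labels
  restamp(agg, x)
}

#' Floor low intensities
#'
#' Values below a linear-scale intensity floor (default 10) are raised to
#' the floor; on a log2 matrix the threshold is \code{log2(floor_linear)}.
#' Intensities near the floor are dominated by array background, so
#' differences below it are noise. Idempotent.
#'
#' @param x An \code{\link{expr_matrix}} (scale tag decides the threshold).
#' @param floor_linear Floor on the linear intensity scale.
#' @return The floored \code{expr_matrix}, scale unchanged.
#' @export
floor_values <- function(x, floor_linear = 10) {
  thr <- switch(expr_scale(x), linear = floor_linear, log2 = log2(floor_linear))
  out <- pmax(unclass(x), thr)
  restamp(out, x)
}

#' Mean-center each gene
#'
#' Subtracts each row's across-sample mean so rows express deviation from
#' their own baseline.
#'
#' @param x An \code{\link{expr_matrix}} with at least 2 samples.
#' @return The centered \code{expr_matrix} (row means 0).
#' @export
mean_center <- function(x) {
  out <- unclass(x) - rowMeans(x)
  restamp(out, x)
}

#' Variation filter
#'
#' Removes rows whose across-sample standard deviation (n - 1 denominator)
#' falls below \code{sd_min}; rows at exactly \code{sd_min} are kept. Row
#' order is otherwise preserved.
#'
#' @param x An \code{\link{expr_matrix}}.
#' @param sd_min Minimum standard deviation to keep a row.
#' @return The filtered \code{expr_matrix}.
#' @export
variation_filter <- function(x, sd_min = 0.5) {
  if (ncol(x) < 2L) stop("variation filter needs at least 2 samples")
  sds <- row_sds(x)
  keep <- sds >= sd_min
  if (!any(keep)) stop("variation filter removed every row")
  restamp(unclass(x)[keep, , drop = FALSE], x)
}

row_sds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((unclass(x) - mu)^2) / (n - 1))
}

#' Collapse probes to gene symbols
#'
#' Probes flagged as hitting multiple genomic loci are removed first; probes
#' absent from the map are dropped (with a message reporting the count).
#' Each gene is then represented by its probe with the highest mean
#' expression across samples (\code{mode = "max_mean"}, the convention of
#' the GSEA desktop software), or by the element-wise maximum across its
#' probes (\code{mode = "max_element"}).
#'
#' @param x A probe-level \code{\link{expr_matrix}}.
#' @param pm A \code{\link{probe_map}}.
#' @param mode Collapse rule.
#' @return A gene-level \code{expr_matrix}; symbols ordered by first probe
#'   appearance, no duplicates.
#' @export
collapse_probes <- function(x, pm, mode = c("max_mean", "max_element")) {
  mode <- match.arg(mode)
  idx <- match(rownames(x), pm$probe)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0L) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)", unmapped))
  }
  keep <- !is.na(idx) & !pm$multi_hit[idx]
  vals <- unclass(x)[keep, , drop = FALSE]
  symbols <- pm$symbol[idx[keep]]
  if (!nrow(vals)) stop("no probes left after multi-hit/unmapped removal")
  out_symbols <- unique(symbols)
  if (mode == "max_mean") {
    means <- rowMeans(vals)
    rep_row <- vapply(out_symbols, function(s) {
      rows <- which(symbols == s)
      rows[which.max(means[rows])]
    }, 0L)
    out <- vals[rep_row, , drop = FALSE]
  } else {
    out <- t(vapply(out_symbols, function(s) {
      apply(vals[symbols == s, , drop = FALSE], 2L, max)
    }, numeric(ncol(vals))))
  }
  rownames(out) <- out_symbols
  restamp(out, x)
}
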