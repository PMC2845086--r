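#' Construct an expression matrix
#'
#' The substrate of every pipeline stage: a genes/probes x samples matrix of
#' intensities with an explicit scale tag. The scale is declared, never
#' sniffed, because the intensity floor is scale-dependent.
#'
#' @param values Numeric matrix; rownames are unique probe or gene
#'   identifiers, colnames are unique sample identifiers.
#' @param scale Either \code{"log2"} (default) or \code{"linear"}.
#' @return A numeric matrix with a \code{scale} attribute and class
#'   \code{"expr_matrix"} prepended.
#' @export
expr_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (features) and colnames (samples)")
  }
  validate_expr_matrix(values)
  attr(values, "scale") <- scale
  class(values) <- c("expr_matrix", class(values))
  values
}

validate_expr_matrix <- function(values) {
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop(sprintf("duplicate row identifier: '%s'", dup))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers")
  }
  if (ncol(values) < 2L) stop("an expression matrix needs at least 2 samples")
  if (any(!is.finite(values))) stop("all expression values must be finite")
  invisible(values)
}

# Rebuild the class/scale attributes after a base-R matrix operation.
restamp <- function(values, template) {
  attr(values, "scale") <- expr_scale(template)
  class(values) <- c("expr_matrix", setdiff(class(values), "expr_matrix"))
  values
}

#' Scale tag of an expression matrix
#' @param x An \code{expr_matrix}.
#' @return \code{"log2"} or \code{"linear"}.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) stop("matrix has no scale tag; construct it with expr_matrix()")
  s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- unclass(x)[i, j, drop = drop]
  if (is.matrix(out)) restamp(out, x) else out
}

#' Construct sample group labels
#'
#' Maps each sample to exactly one group (a leukemia genetic subtype or a
#' tissue type). Every group must contain at least two samples so that
#' within-group variances exist for the one-vs-rest contrasts.
#'
#' @param labels Character or factor vector of group labels, one per sample.
#' @param samples Sample identifiers; defaults to \code{names(labels)}.
#' @return A named factor of class \code{"sample_groups"}.
#' @export
sample_groups <- function(labels, samples = names(labels)) {
  if (is.null(samples)) stop("sample identifiers are required")
  if (length(samples) != length(labels)) stop("one label per sample required")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  f <- factor(as.character(labels), levels = unique(as.character(labels)))
  names(f) <- samples
  sizes <- table(f)
  if (any(sizes < 2L)) {
    bad <- names(sizes)[sizes < 2L][1L]
    stop(sprintf("group '%s' has fewer than 2 samples", bad))
  }
  class(f) <- c("sample_groups", "factor")
  f
}

#' @export
print.sample_groups <- function(x, ...) {
  tab <- table(factor(as.character(x), levels = levels(x)))
  cat(sprintf("sample_groups: %d samples in %d groups\n", length(x), nlevels(x)))
  print(tab)
  invisible(x)
}

#' Construct a probe-to-symbol map
#'
#' @param probe Character vector of unique probe identifiers.
#' @param symbol Gene symbol per probe (non-empty unless the probe is
#'   flagged multi-hit and therefore discarded at collapse).
#' @param multi_hit Logical; probes mapping to multiple genomic loci are
#'   removed before collapsing.
#' @return A \code{data.frame} with class \code{"probe_map"}.
#' @export
probe_map <- function(probe, symbol, multi_hit = FALSE) {
  if (anyDuplicated(probe)) stop("duplicate probe identifiers")
  multi_hit <- rep_len(as.logical(multi_hit), length(probe))
  if (any(!multi_hit & (is.na(symbol) | symbol == ""))) {
    stop("non-discarded probes need a non-empty gene symbol")
  }
  out <- data.frame(probe = as.character(probe), symbol = as.character(symbol),
                    multi_hit = multi_hit, stringsAsFactors = FALSE)
  class(out) <- c("probe_map", "data.frame")
  out
}

#' Construct a gene-set collection
#'
#' Named, directed gene lists. By convention the direction is carried in the
#' set-name suffix (\code{_UP} / \code{_DN}) and the description field stores
#' the source group, which keeps the collection valid GMT.
#'
#' @param sets Named list of character vectors of unique gene symbols.
#' @param description Character vector of per-set descriptions (recycled);
#'   by convention the source group label.
#' @return A named list with class \code{"gene_sets"} and a
#'   \code{description} attribute.
#' @export
gene_sets <- function(sets, description = "") {
  if (length(sets) && is.null(names(sets))) stop("gene sets must be named")
  if (anyDuplicated(names(sets))) {
    stop(sprintf("duplicate gene-set name: '%s'",
                 names(sets)[duplicated(names(sets))][1L]))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  structure(sets, description = description, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Direction of each set in a collection, parsed from the name suffix
#' @param sets A \code{gene_sets} collection.
#' @return Character vector: \code{"up"}, \code{"down"} or \code{NA}.
#' @export
set_directions <- function(sets) {
  nm <- names(sets)
  out <- rep(NA_character_, length(nm))
  out[grepl("_UP$", nm)] <- "up"
  out[grepl("_DN$", nm)] <- "down"
  out
}

#' Combine gene-set collections
#' @param ... \code{gene_sets} collections.
#' @return A single \code{gene_sets} collection; duplicate names are an error.
#' @export
combine_gene_sets <- function(...) {
  colls <- list(...)
  if (length(colls) == 1L && !inherits(colls[[1L]], "gene_sets")) {
    colls <- colls[[1L]]
  }
  sets <- do.call(c, lapply(colls, unclass))
  desc <- do.call(c, lapply(colls, function(x) attr(x, "description")))
  gene_sets(sets, description = desc)
}
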