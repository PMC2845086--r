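# Row-wise two-sample t statistics (one group vs the rest), vectorised.
# Welch by default; the pooled-variance variant is available for
# sensitivity analyses. Per-group variances are floored so degenerate
# (constant) rows yield t = 0 rather than NaN.
welch_t_rows <- function(values, target_idx, var_equal = FALSE,
                         var_floor = 1e-6) {
  n1 <- length(target_idx)
  n2 <- ncol(values) - n1
  stopifnot(n1 >= 2L, n2 >= 2L)
  x1 <- values[, target_idx, drop = FALSE]
  x2 <- values[, -target_idx, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- pmax(rowSums((x1 - m1)^2) / (n1 - 1), var_floor)
  v2 <- pmax(rowSums((x2 - m2)^2) / (n2 - 1), var_floor)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep_len(n1 + n2 - 2, nrow(values))
  } else {
    a1 <- v1 / n1
    a2 <- v2 / n2
    se2 <- a1 + a2
    df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, p = p, df = df)
}

#' One-vs-rest differential statistics for one contrast
#'
#' Computes, per gene, the two-sample t statistic of the target group
#' against all remaining samples (positive t = higher in the target), its
#' two-sided p-value, and the Benjamini-Hochberg adjusted q-value. The
#' default is the unequal-variance (Welch) t with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param x A gene-level \code{\link{expr_matrix}}.
#' @param groups A \code{\link{sample_groups}} aligned to \code{colnames(x)}.
#' @param target Group label to contrast against the rest.
#' @param var_equal Use the pooled-variance t instead of Welch.
#' @param var_floor Lower bound on each group's per-gene variance
#'   (log2 units squared); guards degenerate rows, never produces NaN.
#' @return A \code{data.frame} with columns \code{gene}, \code{t}, \code{p},
#'   \code{q}, \code{direction} (sign of t), in row order of \code{x}.
#' @export
contrast_statistics <- function(x, groups, target, var_equal = FALSE,
                                var_floor = 1e-6) {
  idx <- match_groups(x, groups, target)
  st <- welch_t_rows(unclass(x), idx, var_equal = var_equal,
                     var_floor = var_floor)
  data.frame(gene = rownames(x), t = st$t, p = st$p,
             q = fdr_adjust(st$p), direction = sign(st$t),
             row.names = NULL, stringsAsFactors = FALSE)
}

match_groups <- function(x, groups, target) {
  if (is.null(names(groups)) || !all(colnames(x) %in% names(groups))) {
    stop("`groups` must be named by the matrix's sample identifiers")
  }
  labels <- as.character(groups[colnames(x)])
  if (!target %in% labels) stop(sprintf("no samples in target group '%s'", target))
  idx <- which(labels == target)
  if (length(idx) < 2L) stop(sprintf("target group '%s' has fewer than 2 samples", target))
  if (ncol(x) - length(idx) < 2L) stop("rest group has fewer than 2 samples")
  idx
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values, order-preserving with the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the up/down gene-set database from a reference panel
#'
#' For each group of the panel, genes are ranked by the one-vs-rest t
#' statistic; the list is truncated at \code{fdr_max} (BH q-value), or, when
#' very many genes pass, at \code{cap} genes per direction keeping the
#' largest |t| (ties at the boundary broken by gene symbol for
#' reproducibility). The truncated list is split by sign of t into
#' \code{<group>_UP} and \code{<group>_DN} sets.
#'
#' @param x A gene-level (post-collapse) \code{\link{expr_matrix}}.
#' @param groups A \code{\link{sample_groups}}; every group is used as target.
#' @param fdr_max FDR truncation threshold (q <= fdr_max kept).
#' @param cap Maximum genes retained per direction when more pass the FDR cut.
#' @param cap_scope \code{"per_direction"} truncates up and down lists
#'   independently at \code{cap}; \code{"combined"} truncates the combined
#'   list at \code{cap} before splitting.
#' @param var_equal Passed to \code{\link{contrast_statistics}}.
#' @return A \code{\link{gene_sets}} collection; each set's description is
#'   its source group label. Groups with no passing genes yield empty sets
#'   (removed later by \code{\link{filter_by_size}}) with a warning.
#' @export
build_gene_sets <- function(x, groups, fdr_max = 0.01, cap = 300,
                            cap_scope = c("per_direction", "combined"),
                            var_equal = FALSE) {
  cap_scope <- match.arg(cap_scope)
  sets <- list()
  desc <- character(0)
  for (grp in levels(groups)) {
    st <- contrast_statistics(x, groups, grp, var_equal = var_equal)
    hit <- st[st$q <= fdr_max, , drop = FALSE]
    if (!nrow(hit)) {
      warning(sprintf("no gene passes FDR %.3g for group '%s'; emitting empty sets",
                      fdr_max, grp))
    }
    # order by decreasing |t|, gene symbol breaking boundary ties
    hit <- hit[order(-abs(hit$t), hit$gene), , drop = FALSE]
    if (cap_scope == "combined" && nrow(hit) > cap) {
      hit <- hit[seq_len(cap), , drop = FALSE]
    }
    up <- hit$gene[hit$t > 0]
    dn <- hit$gene[hit$t < 0]
    if (cap_scope == "per_direction") {
      if (length(up) > cap) up <- up[seq_len(cap)]
      if (length(dn) > cap) dn <- dn[seq_len(cap)]
    }
    sets[[paste0(grp, "_UP")]] <- up
    sets[[paste0(grp, "_DN")]] <- dn
    desc <- c(desc, grp, grp)
  }
  gene_sets(sets, description = desc)
}

#' Size-filter a gene-set collection
#'
#' Keeps sets with more than \code{min_exclusive} and fewer than
#' \code{max_exclusive} members (both bounds excluded), optionally after
#' intersecting each set with a gene universe. Removals are logged with
#' name and (post-intersection) size.
#'
#' @param sets A \code{\link{gene_sets}} collection.
#' @param min_exclusive Sets of this size or smaller are removed.
#' @param max_exclusive Sets of this size or larger are removed.
#' @param universe Optional character vector; members outside it are dropped
#'   before sizing.
#' @return A list with elements \code{sets} (the filtered collection) and
#'   \code{excluded} (data.frame of name and size for each removal).
#' @export
filter_by_size <- function(sets, min_exclusive = 15, max_exclusive = 500,
                           universe = NULL) {
  desc <- attr(sets, "description")
  trimmed <- if (is.null(universe)) {
    unclass(sets)
  } else {
    lapply(unclass(sets), function(g) g[g %in% universe])
  }
  sizes <- lengths(trimmed)
  keep <- sizes > min_exclusive & sizes < max_exclusive
  excluded <- data.frame(name = names(trimmed)[!keep],
                         size = unname(sizes[!keep]),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(sets = gene_sets(trimmed[keep], description = desc[keep]),
       excluded = excluded)
}
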