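#' Cross-enrichment matrix: every subtype contrast x every gene set
#'
#' Runs a full phenotype-permutation GSEA for each group of the test
#' dataset (one-vs-rest) against the union of the supplied gene-set
#' collections, assembling the subtype x gene-set grid of NES, p and q
#' values. FDR is estimated within each subtype's run (per GSEA
#' invocation); set \code{global_fdr = TRUE} to re-estimate q jointly
#' across all subtypes from the pooled null.
#'
#' @param x Gene-level test \code{\link{expr_matrix}}.
#' @param groups Test-sample \code{\link{sample_groups}} (genetic subtypes).
#' @param collections A \code{\link{gene_sets}} collection or a list of them
#'   (combined; duplicate names are an error).
#' @param n_perm,weight,min_size,max_size,q_threshold,var_equal As in
#'   \code{\link{run_gsea}}.
#' @param seed Root seed; each subtype's permutations derive a private
#'   stream from it, so cell values do not depend on iteration order.
#' @param global_fdr Recompute q across all subtypes jointly.
#' @return An \code{enrichment_matrix}: list with \code{results} (long
#'   data.frame with a \code{subtype} column), \code{subtypes},
#'   \code{sets} (set metadata), and \code{config}.
#' @export
run_matrix <- function(x, groups, collections, n_perm = 2000, weight = 1,
                       min_size = 15, max_size = 500, q_threshold = 0.25,
                       seed = NULL, var_equal = FALSE, global_fdr = FALSE) {
  sets <- if (inherits(collections, "gene_sets")) collections
          else combine_gene_sets(collections)
  labels <- as.character(groups[colnames(x)])
  sizes <- table(labels)
  subtypes <- levels(groups)[levels(groups) %in% names(sizes)[sizes >= 2L]]
  skipped <- setdiff(levels(groups), subtypes)
  if (length(skipped)) {
    warning(sprintf("skipping subtype(s) with < 2 samples: %s",
                    paste(skipped, collapse = ", ")))
  }
  runs <- lapply(subtypes, function(st) {
    res <- run_gsea(x, groups, st, sets, n_perm = n_perm, weight = weight,
                    min_size = min_size, max_size = max_size,
                    q_threshold = q_threshold, seed = seed,
                    var_equal = var_equal)
    cbind(subtype = rep(st, nrow(res)), res, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, runs)
  rownames(results) <- NULL
  if (global_fdr && nrow(results)) {
    # pooled-null q across the whole grid (config-gated alternative)
    pools <- lapply(subtypes, function(st) {
      null <- permutation_null(x, groups, st, sets, n_perm = n_perm,
                               weight = weight, seed = seed,
                               var_equal = var_equal)
      null_nes_pool(null$es)
    })
    results$q <- fdr_q(results$nes, unlist(pools))
    results$significant <- !is.na(results$q) & results$q <= q_threshold
  }
  set_info <- data.frame(set = names(sets),
                         source = unname(attr(sets, "description")),
                         direction = set_directions(sets),
                         stringsAsFactors = FALSE)
  structure(list(results = results, subtypes = subtypes, sets = set_info,
                 config = list(n_perm = n_perm, weight = weight,
                               min_size = min_size, max_size = max_size,
                               q_threshold = q_threshold, seed = seed,
                               var_equal = var_equal,
                               global_fdr = global_fdr)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d subtypes x %d sets, %d significant cells\n",
              length(x$subtypes), length(unique(x$results$set)),
              sum(x$results$significant)))
  invisible(x)
}

#' Partition significant cells by enrichment direction
#'
#' Splits the significant cells of an enrichment matrix into the up-side
#' report (positive NES: the subtype's upregulated genes are enriched in
#' the set) and the down-side report (negative NES). Every significant cell
#' appears in exactly one report.
#'
#' @param em An \code{enrichment_matrix}.
#' @return A list with data.frames \code{up} and \code{down}.
#' @export
partition_by_direction <- function(em) {
  sig <- em$results[em$results$significant, , drop = FALSE]
  list(up = sig[sig$nes > 0, , drop = FALSE],
       down = sig[sig$nes < 0, , drop = FALSE])
}

fmt_num <- function(v) ifelse(is.na(v), "NA", sprintf("%.10g", v))

#' Export an enrichment matrix as TSV tables
#'
#' Writes four artifacts to \code{dir}: a masked grid TSV (subtype rows x
#' set columns, NES printed only for significant cells, mirroring figures
#' that show scores only for FDR-significant enrichments), a complete long
#' TSV with all ES/NES/p/q values, a leading-edge TSV (one row per
#' significant cell with its core enrichment genes), and a YAML run
#' manifest with all parameters and the seed.
#'
#' @param em An \code{enrichment_matrix}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of file paths.
#' @export
export_matrix <- function(em, dir, prefix = "cross") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- em$results
  paths <- c(masked = file.path(dir, paste0(prefix, "_matrix_masked.tsv")),
             full = file.path(dir, paste0(prefix, "_matrix_full.tsv")),
             leading = file.path(dir, paste0(prefix, "_leading_edge.tsv")),
             manifest = file.path(dir, paste0(prefix, "_manifest.yaml")))

  set_names <- em$sets$set[em$sets$set %in% res$set]
  grid <- vapply(set_names, function(sn) {
    vapply(em$subtypes, function(st) {
      row <- res[res$subtype == st & res$set == sn, , drop = FALSE]
      if (nrow(row) == 1L && row$significant) fmt_num(row$nes) else ""
    }, "")
  }, character(length(em$subtypes)))
  grid <- matrix(grid, nrow = length(em$subtypes),
                 dimnames = list(em$subtypes, set_names))
  writeLines(c(paste(c("subtype", set_names), collapse = "\t"),
               vapply(em$subtypes, function(st) {
                 paste(c(st, grid[st, ]), collapse = "\t")
               }, "")), paths[["masked"]])

  full_cols <- c("subtype", "set", "source", "direction", "size",
                 "es", "nes", "p", "q", "significant")
  lines <- vapply(seq_len(nrow(res)), function(i) {
    paste(c(res$subtype[i], res$set[i], res$source[i], res$direction[i],
            res$size[i], fmt_num(res$es[i]), fmt_num(res$nes[i]),
            fmt_num(res$p[i]), fmt_num(res$q[i]),
            as.integer(res$significant[i])), collapse = "\t")
  }, "")
  writeLines(c(paste(full_cols, collapse = "\t"), lines), paths[["full"]])

  sig <- res[res$significant, , drop = FALSE]
  le_lines <- vapply(seq_len(nrow(sig)), function(i) {
    paste(c(sig$subtype[i], sig$set[i],
            paste(sig$leading_edge[[i]], collapse = ",")), collapse = "\t")
  }, "")
  writeLines(c("subtype\tset\tleading_edge", le_lines), paths[["leading"]])

  yaml::write_yaml(c(em$config, list(subtypes = em$subtypes,
                                     n_sets = nrow(em$sets))),
                   paths[["manifest"]])
  invisible(paths)
}

#' Read back the complete long-table export
#'
#' @param path Path to the \code{*_matrix_full.tsv} written by
#'   \code{\link{export_matrix}}.
#' @return A data.frame with the same columns and values as
#'   \code{em$results} (without the leading-edge list-column).
#' @export
read_matrix_full <- function(path) {
  out <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out$significant <- as.logical(out$significant)
  out
}
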