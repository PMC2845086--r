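#' Read an expression matrix
#'
#' Supports GCT 1.2 (Broad convention: \code{#1.2} version line, declared
#' dimensions, \code{Name}/\code{Description} columns) and a plain TSV
#' dialect (first column row id, header row of sample ids, "." decimal).
#'
#' @param path File path.
#' @param format \code{"gct"} or \code{"tsv"}.
#' @param scale Declared scale of the stored values (not sniffed).
#' @return An \code{\link{expr_matrix}}; row and sample order equal file order.
#' @export
read_expression <- function(path, format = c("gct", "tsv"),
                            scale = c("log2", "linear")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1L], "#1.2")) {
      stop("not a GCT 1.2 file: missing '#1.2' version line")
    }
    dims <- as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][1:2])
    if (any(is.na(dims))) stop("malformed GCT dimension line")
    body <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(body) != dims[1L]) {
      stop(sprintf("GCT declares %d rows but contains %d", dims[1L], nrow(body)))
    }
    if (ncol(body) - 2L != dims[2L]) {
      stop(sprintf("GCT declares %d samples but contains %d",
                   dims[2L], ncol(body) - 2L))
    }
    ids <- as.character(body[[1L]])
    values <- as.matrix(body[, -(1:2), drop = FALSE])
  } else {
    body <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
    ids <- as.character(body[[1L]])
    values <- as.matrix(body[, -1L, drop = FALSE])
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate row identifier: '%s'", ids[duplicated(ids)][1L]))
  }
  storage.mode(values) <- "double"
  rownames(values) <- ids
  expr_matrix(values, scale = scale)
}

#' Write an expression matrix
#'
#' Values are written with enough significant digits to round-trip through
#' \code{\link{read_expression}} to an equal matrix.
#'
#' @param x An \code{\link{expr_matrix}}.
#' @param path Output path.
#' @param format \code{"gct"} or \code{"tsv"}.
#' @export
write_expression <- function(x, path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  validate_expr_matrix(x)
  fmt <- function(v) sprintf("%.10g", v)
  rows <- apply(x, 1L, function(v) paste(fmt(v), collapse = "\t"))
  if (format == "gct") {
    header <- c("#1.2",
                paste(nrow(x), ncol(x), sep = "\t"),
                paste(c("Name", "Description", colnames(x)), collapse = "\t"))
    body <- paste(rownames(x), "na", rows, sep = "\t")
  } else {
    header <- paste(c("id", colnames(x)), collapse = "\t")
    body <- paste(rownames(x), rows, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sample group labels
#'
#' Supports Broad CLS (categorical: \code{n_samples n_classes 1} header) and
#' a two-column TSV (\code{sample<TAB>group}, with header).
#'
#' @param path File path.
#' @param format \code{"cls"} or \code{"tsv"}.
#' @param samples Sample identifiers, required for CLS (the format stores
#'   labels positionally); ignored for TSV.
#' @return A \code{\link{sample_groups}} object, one label per sample in
#'   sample order.
#' @export
read_groups <- function(path, format = c("cls", "tsv"), samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  if (format == "cls") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 3L) stop("malformed CLS: expected 3 lines")
    hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
    toks <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
    if (length(toks) != hdr[1L]) {
      stop(sprintf("CLS declares %d samples but labels %d", hdr[1L], length(toks)))
    }
    class_names <- strsplit(trimws(sub("^#\\s*", "", lines[2L])), "[ \t]+")[[1L]]
    # Tokens may be the class names themselves or 0-based indices into them.
    if (all(grepl("^[0-9]+$", toks))) {
      labels <- class_names[as.integer(toks) + 1L]
    } else {
      labels <- toks
    }
    if (length(unique(labels)) != hdr[2L]) {
      stop(sprintf("CLS declares %d classes but labels use %d",
                   hdr[2L], length(unique(labels))))
    }
    if (is.null(samples)) samples <- paste0("sample_", seq_along(labels))
    if (length(samples) != length(labels)) {
      stop("`samples` length does not match CLS label count")
    }
    sample_groups(labels, samples = samples)
  } else {
    body <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    sample_groups(body[[2L]], samples = as.character(body[[1L]]))
  }
}

#' Write sample group labels
#' @param groups A \code{\link{sample_groups}} object.
#' @param path Output path.
#' @param format \code{"cls"} or \code{"tsv"}.
#' @export
write_groups <- function(groups, path, format = c("cls", "tsv")) {
  format <- match.arg(format)
  if (format == "cls") {
    writeLines(c(paste(length(groups), nlevels(groups), 1),
                 paste("#", paste(levels(groups), collapse = " ")),
                 paste(as.character(groups), collapse = " ")), path)
  } else {
    writeLines(c("sample\tgroup",
                 paste(names(groups), as.character(groups), sep = "\t")), path)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then members, tab-separated. Duplicate
#' members within a line are deduplicated with a warning; duplicate set
#' names are an error.
#'
#' @param path File path.
#' @return A \code{\link{gene_sets}} collection in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", bad[1L]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(members, anyDuplicated, 0L) > 0L)
  if (ndup > 0L) {
    warning(sprintf("%d GMT line(s) contained duplicated members; deduplicated", ndup))
  }
  names(members) <- nm
  gene_sets(members, description = desc)
}

#' Write a GMT gene-set collection
#' @param sets A \code{\link{gene_sets}} collection.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-symbol map
#'
#' TSV with header and columns probe, symbol, multi_hit (0/1 or
#' TRUE/FALSE).
#'
#' @param path File path.
#' @return A \code{\link{probe_map}}.
#' @export
read_probe_map <- function(path) {
  body <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  probe_map(body[[1L]], body[[2L]], as.logical(body[[3L]]))
}

#' Write a probe-to-symbol map
#' @param pm A \code{\link{probe_map}}.
#' @param path Output path.
#' @export
write_probe_map <- function(pm, path) {
  writeLines(c("probe\tsymbol\tmulti_hit",
               paste(pm$probe, pm$symbol, as.integer(pm$multi_hit), sep = "\t")),
             path)
  invisible(path)
}
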