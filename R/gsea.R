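# Order genes by descending score with a deterministic, sign-aware
# tie-break: within a tie the symbols run ascending for positive scores and
# descending for negative ones, so negating every score reverses the list
# exactly (up to ties at zero).
rank_order <- function(scores, symbols, symbol_rank = xtfrm(symbols)) {
  s <- ifelse(scores < 0, -1, 1)
  order(-scores, s * symbol_rank)
}

#' Rank genes for one phenotype contrast
#'
#' Sorts all genes by the descending one-vs-rest t statistic of the target
#' group, the ranked list that the running-sum enrichment score walks
#' (highly expressed in the target to the far left).
#'
#' @inheritParams contrast_statistics
#' @return A named numeric vector: scores in descending order, names are
#'   gene symbols. Ties are broken deterministically (see source).
#' @export
rank_genes <- function(x, groups, target, var_equal = FALSE) {
  idx <- match_groups(x, groups, target)
  t <- welch_t_rows(unclass(x), idx, var_equal = var_equal)$t
  ord <- rank_order(t, rownames(x))
  stats::setNames(t[ord], rownames(x)[ord])
}

# Signed running-sum increments for a ranked list and a hit mask.
# weight = 0: each hit adds 1/n_hits; weight = 1: hits add |score| / sum of
# hit |score|s. Every miss subtracts 1/(N - n_hits).
es_increments <- function(scores, hits, weight) {
  N <- length(scores)
  nh <- sum(hits)
  inc <- numeric(N)
  if (weight == 0) {
    inc[hits] <- 1 / nh
  } else {
    w <- abs(scores[hits])^weight
    sw <- sum(w)
    if (sw == 0) inc[hits] <- 1 / nh else inc[hits] <- w / sw
  }
  inc[!hits] <- -1 / (N - nh)
  inc
}

#' Running-sum enrichment score
#'
#' Walks the ranked gene list accumulating a Kolmogorov-Smirnov-style
#' running sum: up at gene-set hits, down at misses (increments normalised
#' so the walk ends at zero). The enrichment score is the signed extremum of
#' maximum absolute deviation; the leading edge (core enrichment genes) are
#' the hits at or before a positive extremum, or at or after a negative one.
#'
#' @param ranked Named numeric vector from \code{\link{rank_genes}}.
#' @param set Character vector of gene symbols.
#' @param weight Hit-weight exponent: 0 (unweighted, classic KS) or 1
#'   (hits weighted by |score|, the GSEA software default).
#' @return A list: \code{es} (in [-1, 1]), \code{profile} (running sum per
#'   position), \code{extremum} (position of the extremum), \code{size}
#'   (effective set size after intersection with the ranked list),
#'   \code{leading_edge} (gene symbols).
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% set
  nh <- sum(hits)
  if (nh == 0L) stop("set is disjoint from the ranked gene universe")
  if (nh == N) stop("set covers the whole ranked list (miss denominator zero)")
  profile <- cumsum(es_increments(unname(ranked), hits, weight))
  pos <- extremum_pos(profile)
  es <- profile[pos]
  leading <- if (es >= 0) {
    names(ranked)[hits & seq_len(N) <= pos]
  } else {
    names(ranked)[hits & seq_len(N) >= pos]
  }
  list(es = es, profile = profile, extremum = pos, size = nh,
       leading_edge = leading)
}

# Position of the signed extremum. At exact ties of |S| between opposite
# signs (possible with rational increments) the earliest position wins; the
# comparison carries a 1-ulp relative tolerance so the choice is stable
# against summation order.
extremum_pos <- function(profile) {
  a <- abs(profile)
  which(a >= max(a) * (1 - 1e-12))[1L]
}

# ES only, for permutation loops: positions are ranks of the hits in the
# ordered list, scores_sorted the full ordered score vector.
es_value <- function(scores_sorted, hit_mask, weight) {
  profile <- cumsum(es_increments(scores_sorted, hit_mask, weight))
  profile[extremum_pos(profile)]
}

#' Phenotype-permutation null distribution of the enrichment score
#'
#' Shuffles sample labels (target group size preserved), re-ranks all genes
#' with the same one-vs-rest t metric, and recomputes the enrichment score
#' of every set, yielding the null ES samples that normalisation and FDR
#' estimation are based on. When the number of distinct label assignments
#' is at most \code{n_perm}, all of them are enumerated instead (with a
#' message).
#'
#' @inheritParams rank_genes
#' @param sets A \code{\link{gene_sets}} collection (already size-filtered).
#' @param n_perm Number of permutations requested.
#' @param weight Hit-weight exponent, as in \code{\link{enrichment_score}}.
#' @param seed Root seed; permutations are drawn in a private RNG stream
#'   derived from it and the target label, so results do not depend on set
#'   iteration order and do not disturb the caller's RNG.
#' @return A list: \code{es} (matrix, permutations x sets), \code{exhaustive}
#'   (logical), \code{n_perm} (rows actually computed).
#' @export
permutation_null <- function(x, groups, target, sets, n_perm = 2000,
                             weight = 1, seed = NULL, var_equal = FALSE) {
  stopifnot(n_perm >= 1)
  idx <- match_groups(x, groups, target)
  n <- ncol(x)
  k <- length(idx)
  n_distinct <- choose(n, k)
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exhaustive) {
    assign_mat <- utils::combn(n, k)
    message(sprintf(
      "permutation_null: only %d distinct label assignments (< %d requested); enumerating all",
      ncol(assign_mat), n_perm))
  } else {
    assign_mat <- with_seed(derive_seed(seed, target),
                            replicate(n_perm, sample.int(n, k)))
    assign_mat <- matrix(assign_mat, nrow = k)
  }
  values <- unclass(x)
  symbols <- rownames(x)
  symbol_rank <- xtfrm(symbols)
  set_mask <- vapply(sets, function(g) symbols %in% g, logical(nrow(x)))
  n_runs <- ncol(assign_mat)
  es <- matrix(NA_real_, nrow = n_runs, ncol = length(sets),
               dimnames = list(NULL, names(sets)))
  for (b in seq_len(n_runs)) {
    t <- welch_t_rows(values, assign_mat[, b], var_equal = var_equal)$t
    ord <- rank_order(t, symbols, symbol_rank)
    scores_sorted <- t[ord]
    for (j in seq_along(sets)) {
      es[b, j] <- es_value(scores_sorted, set_mask[ord, j], weight)
    }
  }
  list(es = es, exhaustive = exhaustive, n_perm = n_runs)
}

#' Normalise an enrichment score and compute its nominal p-value
#'
#' NES is the observed ES divided by the mean magnitude of same-sign null
#' ES; the nominal p is the add-one permutation estimate among same-sign
#' nulls, so it is never exactly zero at finite permutations.
#'
#' @param es_obs Observed enrichment score for one set.
#' @param es_null Numeric vector of null ES for the same set.
#' @return A list: \code{nes} (NA with a warning when no same-sign nulls
#'   exist), \code{p} (nominal p-value).
#' @export
normalize_and_test <- function(es_obs, es_null) {
  if (!length(es_null)) stop("at least one null ES sample is required")
  if (es_obs == 0) return(list(nes = 0, p = 1))
  same <- if (es_obs > 0) es_null[es_null > 0] else es_null[es_null < 0]
  if (!length(same)) {
    warning("no same-sign null ES samples; NES undefined")
    return(list(nes = NA_real_, p = 1))
  }
  nes <- es_obs / abs(mean(same))
  p <- (1 + sum(abs(same) >= abs(es_obs))) / (1 + length(same))
  list(nes = nes, p = p)
}

# Null NES pool: every null ES of a set, normalised by that set's same-sign
# null mean magnitude (the pool that permutation FDR compares against).
null_nes_pool <- function(es_null_mat) {
  unlist(lapply(seq_len(ncol(es_null_mat)), function(j) {
    v <- es_null_mat[, j]
    pos <- v[v > 0]
    neg <- v[v < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / abs(mean(neg)))
  }), use.names = FALSE)
}

#' Permutation FDR q-values from pooled null NES
#'
#' For a set with positive NES*, q is the fraction of pooled positive null
#' NES at least as large, divided by the fraction of observed positive NES
#' at least as large, clipped at 1 (mirrored for negative NES).
#' Monotonicity in |NES| is enforced per sign by a running minimum from the
#' least extreme set towards the most extreme.
#'
#' @param nes_obs Numeric vector of observed NES (may contain NA).
#' @param nes_null Pooled null NES (both signs).
#' @return q-values aligned with \code{nes_obs}; NA where NES is NA.
#' @export
fdr_q <- function(nes_obs, nes_null) {
  q <- rep(NA_real_, length(nes_obs))
  null_pos <- nes_null[nes_null > 0]
  null_neg <- nes_null[nes_null < 0]
  for (side in c(1, -1)) {
    ii <- which(!is.na(nes_obs) & sign(nes_obs) == side)
    if (!length(ii)) next
    obs <- nes_obs[ii]
    nulls <- if (side > 0) null_pos else null_neg
    raw <- vapply(obs, function(v) {
      num <- if (length(nulls)) mean(abs(nulls) >= abs(v)) else 0
      den <- mean(abs(obs) >= abs(v))
      min(1, num / den)
    }, 0)
    # running minimum from least extreme towards most extreme
    ord <- order(abs(obs), decreasing = TRUE)
    raw_sorted <- raw[ord]
    mono <- rev(cummin(rev(raw_sorted)))
    q[ii[ord]] <- mono
  }
  q
}

#' Run a full GSEA for one phenotype contrast
#'
#' Size-filters the collection against the matrix's gene universe, ranks
#' genes by the one-vs-rest t statistic, computes each set's running-sum
#' enrichment score and leading edge, builds the phenotype-permutation null,
#' and reports NES, nominal p and permutation FDR q per set; sets with
#' q at or below \code{q_threshold} are flagged significant.
#'
#' @inheritParams permutation_null
#' @param min_size,max_size Exclusive size bounds applied after intersecting
#'   each set with the gene universe.
#' @param q_threshold FDR significance threshold.
#' @return A \code{data.frame} (one row per retained set): \code{set},
#'   \code{source}, \code{direction}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{q}, \code{significant}, and a list-column
#'   \code{leading_edge}. Attributes record the target, permutation count,
#'   seed, exhaustive flag and excluded sets.
#' @export
run_gsea <- function(x, groups, target, sets, n_perm = 2000, weight = 1,
                     min_size = 15, max_size = 500, q_threshold = 0.25,
                     seed = NULL, var_equal = FALSE) {
  flt <- filter_by_size(sets, min_exclusive = min_size,
                        max_exclusive = max_size, universe = rownames(x))
  kept <- flt$sets
  ranked <- rank_genes(x, groups, target, var_equal = var_equal)
  empty <- data.frame(set = character(0), source = character(0),
                      direction = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(kept)) {
    empty$leading_edge <- I(list())
    attr(empty, "excluded") <- flt$excluded
    return(empty)
  }
  obs <- lapply(kept, function(g) enrichment_score(ranked, g, weight = weight))
  null <- permutation_null(x, groups, target, kept, n_perm = n_perm,
                           weight = weight, seed = seed,
                           var_equal = var_equal)
  es_obs <- vapply(obs, `[[`, 0, "es")
  norm <- lapply(seq_along(kept), function(j) {
    suppressWarnings(normalize_and_test(es_obs[j], null$es[, j]))
  })
  nes <- vapply(norm, `[[`, 0, "nes")
  p <- vapply(norm, `[[`, 0, "p")
  q <- fdr_q(nes, null_nes_pool(null$es))
  out <- data.frame(set = names(kept),
                    source = unname(attr(kept, "description")),
                    direction = set_directions(kept),
                    size = vapply(obs, `[[`, 0L, "size"),
                    es = unname(es_obs), nes = nes, p = p, q = q,
                    significant = !is.na(q) & q <= q_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$leading_edge <- I(unname(lapply(obs, `[[`, "leading_edge")))
  attr(out, "target") <- target
  attr(out, "n_perm") <- null$n_perm
  attr(out, "exhaustive") <- null$exhaustive
  attr(out, "seed") <- seed
  attr(out, "excluded") <- flt$excluded
  out
}
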