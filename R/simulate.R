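#' Describe a linked synthetic study design
#'
#' Specifies two linked expression datasets on a shared gene universe: a
#' "test" dataset with genetic-subtype groups (leukemia-like) and a
#' "reference" panel with tissue groups, each group carrying planted
#' up/down expression modules. Overlap entries make a subtype module share
#' \code{floor(rho * size)} genes with a reference module, which is the
#' ground truth that cross-dataset enrichment should recover.
#'
#' Defaults emulate the scale of the study the pipeline is meant for:
#' a handful of tissue groups with ~10 profiles each, a few leukemia
#' subtypes with ~12 samples each, 100-gene programs, mean shifts of
#' 1.5 log2 units over unit-SD noise, and one planted 50% overlap.
#'
#' @param n_genes Size of the shared gene universe.
#' @param reference_groups data.frame with columns \code{label},
#'   \code{n_samples}, \code{up_size}, \code{down_size}.
#' @param test_subtypes Same structure for the test dataset.
#' @param effect Planted mean shift, log2 units.
#' @param noise_sd I.i.d. Gaussian noise SD, log2 units.
#' @param overlap data.frame with columns \code{subtype}, \code{reference},
#'   \code{subtype_direction}, \code{reference_direction}, \code{rho}.
#' @param baseline_mean,baseline_sd Per-gene baseline intensity
#'   distribution (log2), shared between the two datasets.
#' @param seed Root seed for reproducible generation.
#' @return A list of class \code{synthetic_design}.
#' @export
synthetic_design <- function(n_genes = 5000,
                             reference_groups = data.frame(
                               label = sprintf("tissue_%02d", 1:5),
                               n_samples = 10L, up_size = 100L,
                               down_size = 100L),
                             test_subtypes = data.frame(
                               label = c("ETV6_RUNX1", "HeH", "TCF3_PBX1"),
                               n_samples = 12L, up_size = 100L,
                               down_size = 100L),
                             effect = 1.5, noise_sd = 1.0,
                             overlap = data.frame(
                               subtype = "ETV6_RUNX1",
                               reference = "tissue_01",
                               subtype_direction = "up",
                               reference_direction = "up",
                               rho = 0.5),
                             baseline_mean = 7, baseline_sd = 1,
                             seed = 1L) {
  d <- list(n_genes = as.integer(n_genes),
            reference_groups = reference_groups,
            test_subtypes = test_subtypes,
            effect = effect, noise_sd = noise_sd, overlap = overlap,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            seed = as.integer(seed))
  need <- sum(reference_groups$up_size, reference_groups$down_size)
  if (need > n_genes) stop("reference modules exceed the gene universe")
  need_t <- sum(test_subtypes$up_size, test_subtypes$down_size)
  if (need_t > n_genes) stop("test modules exceed the gene universe")
  if (nrow(overlap)) {
    if (!all(overlap$subtype %in% test_subtypes$label) ||
        !all(overlap$reference %in% reference_groups$label)) {
      stop("overlap entries must name existing groups")
    }
    if (any(overlap$rho < 0 | overlap$rho > 1)) stop("rho must lie in [0, 1]")
  }
  structure(d, class = "synthetic_design")
}

# Draw module gene lists for one dataset: modules are pairwise disjoint
# within the dataset; `forced` pins named genes into a module (used to plant
# cross-dataset overlap).
draw_modules <- function(spec, universe, forced = list()) {
  taken <- character(0)
  modules <- list()
  for (i in seq_len(nrow(spec))) {
    for (dir in c("up", "down")) {
      size <- spec[[paste0(dir, "_size")]][i]
      key <- paste0(spec$label[i], ".", dir)
      pinned <- intersect(forced[[key]] %||% character(0), universe)
      free <- setdiff(universe, c(taken, pinned))
      extra <- sample(free, size - length(pinned))
      modules[[key]] <- sort(c(pinned, extra))
      taken <- c(taken, modules[[key]])
    }
  }
  modules
}

#' Generate linked synthetic expression datasets
#'
#' Each value is baseline_g + effect for genes in the sample group's
#' up-module, - effect for its down-module, plus i.i.d. Gaussian noise.
#' Baselines are drawn once per gene and shared between the two datasets so
#' gene-set transfer across them is meaningful. Overlapping modules share
#' exactly \code{floor(rho * size)} genes; all other modules are pairwise
#' disjoint across both datasets, so non-overlap (subtype, set) cells are
#' true nulls.
#'
#' @param design A \code{\link{synthetic_design}}.
#' @return A list: \code{test} and \code{reference}, each with elements
#'   \code{x} (\code{\link{expr_matrix}}, log2) and \code{groups}
#'   (\code{\link{sample_groups}}); and \code{truth} with the per-dataset
#'   module gene lists and the planted shared gene lists per overlap entry.
#' @export
generate_datasets <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    universe <- sprintf("g%05d", seq_len(design$n_genes))
    ref_modules <- draw_modules(design$reference_groups, universe)
    # overlap: pin floor(rho * subtype module size) reference-module genes
    # into the subtype's module
    forced <- list()
    shared <- list()
    ov <- design$overlap
    for (i in seq_len(nrow(ov))) {
      skey <- paste0(ov$subtype[i], ".", ov$subtype_direction[i])
      rkey <- paste0(ov$reference[i], ".", ov$reference_direction[i])
      size <- design$test_subtypes[[paste0(ov$subtype_direction[i], "_size")]][
        match(ov$subtype[i], design$test_subtypes$label)]
      n_shared <- floor(ov$rho[i] * size)
      shared[[paste(skey, rkey, sep = "~")]] <-
        sort(sample(ref_modules[[rkey]], n_shared))
      forced[[skey]] <- c(forced[[skey]],
                          shared[[paste(skey, rkey, sep = "~")]])
    }
    # non-overlap test-module genes avoid every reference module, keeping
    # unplanted cells null
    free_universe <- setdiff(universe, unlist(ref_modules))
    test_modules <- draw_modules(design$test_subtypes,
                                 c(free_universe, unique(unlist(forced))),
                                 forced = forced)
    baseline <- stats::rnorm(design$n_genes, design$baseline_mean,
                             design$baseline_sd)
    names(baseline) <- universe

    build <- function(spec, modules, tag) {
      n_samples <- sum(spec$n_samples)
      labels <- rep(spec$label, spec$n_samples)
      sample_ids <- unlist(lapply(seq_len(nrow(spec)), function(i) {
        sprintf("%s_%s_%02d", tag, spec$label[i], seq_len(spec$n_samples[i]))
      }))
      mu <- matrix(baseline, nrow = design$n_genes, ncol = n_samples,
                   dimnames = list(universe, sample_ids))
      for (i in seq_len(nrow(spec))) {
        cols <- which(labels == spec$label[i])
        up <- modules[[paste0(spec$label[i], ".up")]]
        dn <- modules[[paste0(spec$label[i], ".down")]]
        mu[up, cols] <- mu[up, cols] + design$effect
        mu[dn, cols] <- mu[dn, cols] - design$effect
      }
      vals <- mu + matrix(stats::rnorm(length(mu), 0, design$noise_sd),
                          nrow = nrow(mu))
      list(x = expr_matrix(vals, scale = "log2"),
           groups = sample_groups(labels, samples = sample_ids))
    }
    reference <- build(design$reference_groups, ref_modules, "ref")
    test <- build(design$test_subtypes, test_modules, "tst")
    list(test = test, reference = reference,
         truth = list(test_modules = test_modules,
                      reference_modules = ref_modules, shared = shared))
  })
}

#' Wrap a gene-level matrix in a synthetic probe layer
#'
#' Duplicates each gene into 1-3 probes (gene value plus small probe
#' offsets) and flags a fraction of probes as multi-hit, to exercise the
#' probe-collapse step.
#'
#' @param x A gene-level \code{\link{expr_matrix}}.
#' @param seed Seed.
#' @param multi_hit_frac Fraction of probes flagged multi-hit.
#' @return A list: \code{x} (probe-level matrix), \code{map}
#'   (\code{\link{probe_map}}).
#' @export
add_probe_layer <- function(x, seed = 1L, multi_hit_frac = 0.05) {
  with_seed(seed, {
    genes <- rownames(x)
    n_probes <- sample(1:3, length(genes), replace = TRUE)
    gene_of_probe <- rep(genes, n_probes)
    probe_ids <- sprintf("%s_at%d", gene_of_probe,
                         unlist(lapply(n_probes, seq_len)))
    offsets <- stats::rnorm(length(probe_ids), 0, 0.25)
    vals <- unclass(x)[gene_of_probe, , drop = FALSE] + offsets
    rownames(vals) <- probe_ids
    multi <- stats::runif(length(probe_ids)) < multi_hit_frac
    list(x = restamp(vals, x),
         map = probe_map(probe_ids, gene_of_probe, multi))
  })
}

#' Resample group labels under the null
#'
#' Randomly reassigns group labels to samples, preserving group sizes —
#' exchangeable labels for calibration experiments.
#'
#' @param groups A \code{\link{sample_groups}}.
#' @param seed Seed.
#' @return A \code{sample_groups} with the same samples and group-size
#'   multiset.
#' @export
null_resample <- function(groups, seed = NULL) {
  with_seed(seed, {
    sample_groups(sample(as.character(groups)), samples = names(groups))
  })
}
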