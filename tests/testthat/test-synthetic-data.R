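test_that("designs validate module feasibility and overlap entries", {
  expect_error(synthetic_design(n_genes = 100), "exceed the gene universe")
  expect_error(
    synthetic_design(n_genes = 2000,
                     overlap = data.frame(subtype = "nope", reference = "tissue_01",
                                          subtype_direction = "up",
                                          reference_direction = "up", rho = 0.5)),
    "existing groups")
  expect_error(
    synthetic_design(n_genes = 2000,
                     overlap = data.frame(subtype = "HeH", reference = "tissue_01",
                                          subtype_direction = "up",
                                          reference_direction = "up", rho = 1.5)),
    "rho")
})

test_that("generation is seed-reproducible with the documented structure", {
  d <- synthetic_design(n_genes = 1000,
                        reference_groups = data.frame(label = c("t1", "t2"),
                                                      n_samples = 5L,
                                                      up_size = 50L,
                                                      down_size = 50L),
                        test_subtypes = data.frame(label = c("s1", "s2"),
                                                   n_samples = 6L,
                                                   up_size = 50L, down_size = 50L),
                        overlap = data.frame(subtype = "s1", reference = "t1",
                                             subtype_direction = "up",
                                             reference_direction = "up",
                                             rho = 0.5),
                        seed = 23L)
  g1 <- generate_datasets(d)
  g2 <- generate_datasets(d)
  expect_identical(unclass(g1$test$x), unclass(g2$test$x))
  expect_identical(g1$truth, g2$truth)

  # dimensions and grouping
  expect_equal(dim(g1$test$x), c(1000L, 12L))
  expect_equal(dim(g1$reference$x), c(1000L, 10L))
  expect_equal(as.vector(table(g1$reference$groups)), c(5L, 5L))

  # overlap: exactly floor(rho * size) shared genes, all inside both modules
  shared <- g1$truth$shared[[1]]
  expect_length(shared, 25L)
  expect_true(all(shared %in% g1$truth$test_modules[["s1.up"]]))
  expect_true(all(shared %in% g1$truth$reference_modules[["t1.up"]]))

  # modules within a dataset are pairwise disjoint
  tm <- g1$truth$test_modules
  expect_length(intersect(tm[["s1.up"]], tm[["s1.down"]]), 0)
  expect_length(intersect(tm[["s1.up"]], tm[["s2.up"]]), 0)

  # non-overlap test modules avoid every reference module (null cells stay null)
  ref_all <- unlist(g1$truth$reference_modules)
  expect_length(intersect(setdiff(tm[["s1.up"]], shared), ref_all), 0)
  expect_length(intersect(tm[["s2.down"]], ref_all), 0)
})

test_that("rho = 1 makes the subtype module contain the reference module", {
  d <- synthetic_design(n_genes = 1500,
                        reference_groups = data.frame(label = "t1", n_samples = 4L,
                                                      up_size = 40L, down_size = 40L),
                        test_subtypes = data.frame(label = c("s1", "s2"),
                                                   n_samples = 4L,
                                                   up_size = 40L, down_size = 40L),
                        overlap = data.frame(subtype = "s1", reference = "t1",
                                             subtype_direction = "up",
                                             reference_direction = "up", rho = 1),
                        seed = 3L)
  g <- generate_datasets(d)
  expect_setequal(g$truth$shared[[1]], g$truth$test_modules[["s1.up"]])
  expect_true(all(g$truth$shared[[1]] %in% g$truth$reference_modules[["t1.up"]]))
})

test_that("planted genes carry systematically extreme contrast statistics", {
  for (seed in c(5L, 6L, 7L)) {
    d <- synthetic_design(n_genes = 1200,
                          reference_groups = data.frame(label = c("t1", "t2"),
                                                        n_samples = 8L,
                                                        up_size = 60L,
                                                        down_size = 60L),
                          test_subtypes = data.frame(label = c("s1", "s2"),
                                                     n_samples = 4L,
                                                     up_size = 0L, down_size = 0L),
                          overlap = data.frame(subtype = character(0),
                                               reference = character(0),
                                               subtype_direction = character(0),
                                               reference_direction = character(0),
                                               rho = numeric(0)),
                          seed = seed)
    g <- generate_datasets(d)
    st <- contrast_statistics(g$reference$x, g$reference$groups, "t1")
    planted <- st$gene %in% unlist(g$truth$reference_modules[c("t1.up", "t1.down")])
    expect_gt(mean(abs(st$t[planted])), mean(abs(st$t[!planted])))
    # up-module genes have positive t, down-module negative
    up <- st$gene %in% g$truth$reference_modules[["t1.up"]]
    expect_gt(mean(st$t[up] > 0), 0.95)
  }
})

test_that("effect = 0 produces a null dataset with no extreme module shift", {
  d <- synthetic_design(n_genes = 800,
                        reference_groups = data.frame(label = c("t1", "t2"),
                                                      n_samples = 6L,
                                                      up_size = 50L, down_size = 50L),
                        test_subtypes = data.frame(label = c("s1", "s2"),
                                                   n_samples = 6L,
                                                   up_size = 50L, down_size = 50L),
                        overlap = data.frame(subtype = "s1", reference = "t1",
                                             subtype_direction = "up",
                                             reference_direction = "up", rho = 0.5),
                        effect = 0, noise_sd = 1, seed = 13L)
  g <- generate_datasets(d)
  st <- contrast_statistics(g$reference$x, g$reference$groups, "t1")
  expect_true(all(st$q > 0.01))  # nothing passes a 1% FDR in pure noise
})

test_that("null_resample preserves the group-size multiset and is seeded", {
  g <- sample_groups(rep(c("A", "B", "C"), c(4, 6, 2)),
                     samples = sprintf("s%02d", 1:12))
  r1 <- null_resample(g, seed = 11)
  r2 <- null_resample(g, seed = 11)
  expect_identical(as.character(r1), as.character(r2))
  expect_identical(names(r1), names(g))
  expect_equal(sort(as.vector(table(r1))), sort(as.vector(table(g))))
  r3 <- null_resample(g, seed = 12)
  expect_false(identical(as.character(r1), as.character(r3)))
})

test_that("null_resample is uniform over assignments on an enumerable case", {
  g <- sample_groups(c("A", "A", "B", "B"), samples = paste0("s", 1:4))
  draws <- withr::with_seed(404, {
    replicate(3000, paste(as.character(null_resample(g)), collapse = ""))
  })
  tab <- table(draws)
  expect_equal(length(tab), 6L)  # C(4,2) distinct assignments
  chi <- suppressWarnings(chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
})

test_that("the probe layer exercises collapse back to gene level", {
  x <- rand_expr(80, 6, seed = 261)
  pl <- add_probe_layer(x, seed = 8, multi_hit_frac = 0.1)
  expect_gte(nrow(pl$x), nrow(x))
  collapsed <- collapse_probes(pl$x, pl$map)
  # genes whose probes were all multi-hit disappear; the rest survive uniquely
  surviving <- unique(pl$map$symbol[!pl$map$multi_hit])
  expect_setequal(rownames(collapsed), surviving)
  expect_false(anyDuplicated(rownames(collapsed)) > 0)
})
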