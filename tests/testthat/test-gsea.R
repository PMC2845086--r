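test_that("running sum matches forced singleton cases", {
  ranked <- setNames(c(3, 2, 1, 0.5), paste0("g", 1:4))
  top <- enrichment_score(ranked, "g1", weight = 0)
  expect_equal(top$profile, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(top$es, 1.0)
  expect_equal(top$leading_edge, "g1")

  bottom <- enrichment_score(ranked, "g4", weight = 0)
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$extremum, 3L)
  expect_equal(bottom$leading_edge, "g4")
})

test_that("running sum rejects degenerate sets", {
  ranked <- setNames(c(2, 1, 0), paste0("g", 1:3))
  expect_error(enrichment_score(ranked, "absent"), "disjoint")
  expect_error(enrichment_score(ranked, paste0("g", 1:3)), "whole ranked list")
})

test_that("ES equals the brute-force enumeration on random instances", {
  withr::with_seed(171, {
    for (rep in 1:300) {
      inst <- rand_es_instance(50)
      ranked <- setNames(inst$scores, inst$genes)
      for (w in c(0, 1)) {
        got <- enrichment_score(ranked, inst$set, weight = w)
        want <- brute_es(inst$genes, inst$scores, inst$set, w)
        expect_equal(got$es, want$es, tolerance = 1e-10)
        expect_equal(got$profile, want$profile, tolerance = 1e-10)
        expect_lt(abs(want$final), 1e-9)       # conservation: walk ends at 0
        expect_true(got$es >= -1 && got$es <= 1)
      }
    }
  })
})

test_that("weighted ES agrees with an independent implementation", {
  withr::with_seed(181, {
    for (rep in 1:50) {
      inst <- rand_es_instance(200)
      ranked <- setNames(inst$scores, inst$genes)
      got <- enrichment_score(ranked, inst$set, weight = 1)$es
      ref <- fgsea::calcGseaStat(ranked, which(inst$genes %in% inst$set),
                                 gseaParam = 1, returnAllExtremes = FALSE)
      expect_equal(got, unname(ref), tolerance = 1e-8)
    }
  })
})

test_that("leading edge contains the hits driving the extremum", {
  ranked <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.2, 0.1), paste0("g", 1:8))
  res <- enrichment_score(ranked, c("g1", "g2", "g8"), weight = 0)
  expect_gt(res$es, 0)
  expect_setequal(res$leading_edge, c("g1", "g2"))
  expect_true(all(res$leading_edge %in% c("g1", "g2", "g8")))
  expect_lte(length(res$leading_edge), res$size)
})

test_that("gene ranking sorts by descending t and reverses under label swap", {
  x <- rand_expr(80, 10, seed = 191)
  g <- two_groups(x, 4)
  ranked <- rank_genes(x, g, "case")
  expect_true(all(diff(unname(ranked)) <= 0))
  st <- contrast_statistics(x, g, "case")
  expect_setequal(names(ranked), st$gene)
  expect_equal(unname(ranked[1]), max(st$t))

  swapped <- rank_genes(x, g, "ctrl")
  expect_identical(names(swapped), rev(names(ranked)))
  expect_identical(unname(swapped), -rev(unname(ranked)))
})

test_that("permutation null is seed-reproducible and enumerates when small", {
  x <- rand_expr(60, 10, seed = 201)
  g <- two_groups(x, 5)
  sets <- gene_sets(list(S1_UP = rownames(x)[1:20], S2_DN = rownames(x)[21:40]))
  a <- permutation_null(x, g, "case", sets, n_perm = 50, seed = 9)
  b <- permutation_null(x, g, "case", sets, n_perm = 50, seed = 9)
  expect_identical(a$es, b$es)
  c2 <- permutation_null(x, g, "case", sets, n_perm = 50, seed = 10)
  expect_false(identical(a$es, c2$es))
  expect_true(all(a$es >= -1 & a$es <= 1))

  # 2 target + 2 rest: C(4,2) = 6 distinct assignments -> exhaustive mode
  xs <- rand_expr(30, 4, seed = 211)
  gs <- two_groups(xs, 2)
  small_sets <- gene_sets(list(S_UP = rownames(xs)[1:10]))
  expect_message(
    ex <- permutation_null(xs, gs, "case", small_sets, n_perm = 100, seed = 1),
    "enumerating all")
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 6L)
})

test_that("NES and nominal p follow their permutation definitions", {
  null <- c(0.5, 0.3, 0.2, -0.4, -0.1)
  # ES equal to the same-sign null mean -> NES = 1
  r <- normalize_and_test(mean(c(0.5, 0.3, 0.2)), null)
  expect_equal(r$nes, 1.0)
  # more extreme than all k = 3 positive nulls -> p = 1/(k+1)
  r2 <- normalize_and_test(0.9, null)
  expect_equal(r2$p, 1 / 4)
  expect_equal(r2$nes, 0.9 / mean(c(0.5, 0.3, 0.2)))
  # negative side keeps the sign
  r3 <- normalize_and_test(-0.3, null)
  expect_lt(r3$nes, 0)
  expect_equal(r3$nes, -0.3 / 0.25)
  # no same-sign nulls -> missing NES with a warning
  expect_warning(r4 <- normalize_and_test(-0.2, c(0.1, 0.4)), "NES undefined")
  expect_true(is.na(r4$nes))
})

test_that("pooled-null FDR q behaves at its limits and stays monotone", {
  # single set above every pooled null -> q = 0
  expect_equal(fdr_q(2.5, c(1.1, 0.8, 1.3, -0.9)), 0)
  # observed distribution identical to the null -> q near 1
  obs <- c(0.5, 1, 1.5, 2, -0.5, -1.5)
  q <- fdr_q(obs, rep(obs, 50))
  expect_true(all(q[abs(obs) < 2] > 0.6))
  # monotone: larger |NES| never gets a larger q within a sign
  withr::with_seed(221, {
    for (rep in 1:20) {
      o <- rnorm(12); nl <- rnorm(400)
      qq <- fdr_q(o, nl)
      pos <- order(o[o > 0], decreasing = TRUE)
      expect_true(all(diff(qq[o > 0][pos]) >= -1e-12))
      neg <- order(o[o < 0])
      expect_true(all(diff(qq[o < 0][neg]) >= -1e-12))
      expect_true(all(qq <= 1 & qq >= 0, na.rm = TRUE))
    }
  })
})

test_that("a planted top-gene set comes out significant with NES > 1", {
  vals <- unclass(rand_expr(400, 12, seed = 231))
  vals[1:50, 1:6] <- vals[1:50, 1:6] + 2
  x <- expr_matrix(vals)
  g <- two_groups(x, 6)
  sets <- gene_sets(list(PLANTED_UP = rownames(x)[1:50],
                         RANDOM_A = rownames(x)[101:150],
                         RANDOM_B = rownames(x)[201:260]))
  res <- run_gsea(x, g, "case", sets, n_perm = 200, seed = 12)
  planted <- res[res$set == "PLANTED_UP", ]
  expect_true(planted$significant)
  expect_gt(planted$nes, 1)
  expect_gt(planted$es, 0)
  expect_true(all(planted$leading_edge[[1]] %in% rownames(x)[1:50]))

  # empty collection -> empty result
  none <- run_gsea(x, g, "case", gene_sets(list()), n_perm = 10, seed = 1)
  expect_equal(nrow(none), 0L)
})

test_that("run_gsea is deterministic given a seed", {
  x <- rand_expr(150, 10, seed = 241)
  g <- two_groups(x, 5)
  sets <- gene_sets(list(A_UP = rownames(x)[1:30], B_DN = rownames(x)[40:80]))
  r1 <- run_gsea(x, g, "case", sets, n_perm = 100, seed = 77)
  r2 <- run_gsea(x, g, "case", sets, n_perm = 100, seed = 77)
  expect_identical(r1$es, r2$es)
  expect_identical(r1$nes, r2$nes)
  expect_identical(r1$q, r2$q)
})
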