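test_that("phenotype assignment uses a strict below-threshold rule", {
  mat <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        c1 = c(-4.5, -4, 0), c2 = c(0, -7, 0))
  ph <- phenotypes_from_scores(mat, threshold = -4)
  expect_equal(ph$gene, c("g1", "g2"))
  expect_equal(ph$condition, c("c1", "c2"))  # -4 exactly is NOT assigned

  all_zero <- phenotypes_from_scores(tibble::tibble(gene = "g1", c1 = 0))
  expect_equal(nrow(all_zero), 0)
})

test_that("accuracy-coverage curve matches hand enumeration", {
  # three links, share pattern [yes, yes, no], bin size 1
  net <- toy_network(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                     lls = c(3, 2, 1), evidence = "X")
  mat <- tibble::tibble(gene = c("a", "b", "c", "d", "e", "f"),
                        s1 = c(-5, -5, 0, 0, -5, 0),
                        s2 = c(0, 0, -5, -5, 0, -5))
  ph <- phenotypes_from_scores(mat)
  curve <- accuracy_coverage_curve(net, ph, bin_size = 1, total_coding_genes = 6)
  expect_equal(curve$accuracy, c(100, 100, 200 / 3), tolerance = 1e-10)
  expect_equal(curve$coverage, c(100 * 2 / 6, 100 * 4 / 6, 100))
  expect_true(all(diff(curve$coverage) >= 0))

  # all pairs sharing -> flat 100% curve
  flat_ph <- phenotypes_from_scores(
    tibble::tibble(gene = c("a", "b", "c", "d", "e", "f"), s1 = rep(-9, 6)))
  flat <- accuracy_coverage_curve(net, flat_ph, bin_size = 1,
                                  total_coding_genes = 6)
  expect_true(all(flat$accuracy == 100))

  # non-evaluable prefix -> missing accuracy, point still emitted
  ph2 <- phenotypes_from_scores(
    tibble::tibble(gene = c("c", "d"), s1 = c(-9, -9)))
  curve2 <- accuracy_coverage_curve(net, ph2, bin_size = 1,
                                    total_coding_genes = 6)
  expect_true(is.na(curve2$accuracy[1]))
  expect_equal(curve2$accuracy[2], 100)
})

test_that("a 4099-gene network over a 4146-gene genome reports ~99% coverage", {
  n <- 4099
  genes <- sprintf("g%04d", seq_len(n))
  chain <- toy_network(gene_a = genes[-n], gene_b = genes[-1],
                       lls = rep(1, n - 1), evidence = "X")
  ph <- phenotypes_from_scores(tibble::tibble(gene = genes[1:10], s1 = -9))
  curve <- accuracy_coverage_curve(chain, ph, bin_size = 1000,
                                   total_coding_genes = 4146)
  expect_equal(round(curve$coverage[nrow(curve)]), 99)
})

test_that("leave-one-out AUC handles perfect, inverted and fully tied rankings", {
  # star: members m1..m3 all strongly interconnected, decoys unconnected
  members <- c("m1", "m2", "m3")
  net <- toy_network(gene_a = c("m1", "m1", "m2"),
                     gene_b = c("m2", "m3", "m3"),
                     lls = c(3, 3, 3), evidence = "X")
  universe <- c(members, sprintf("d%02d", 1:20))
  expect_equal(as.numeric(loo_auc(net, members, universe)), 1)

  # held-out member always bottom: decoys all connected, member not
  net2 <- toy_network(gene_a = rep(c("m1", "m2"), each = 3),
                      gene_b = rep(c("d1", "d2", "d3"), 2),
                      lls = rep(2, 6), evidence = "X")
  auc2 <- suppressWarnings(loo_auc(net2, members, c(members, c("d1", "d2", "d3"))))
  expect_equal(as.numeric(auc2), 0)

  # every candidate tied at zero -> midrank AUC 0.5
  net3 <- toy_network(gene_a = "z1", gene_b = "z2", lls = 1, evidence = "X")
  auc3 <- suppressWarnings(loo_auc(net3, members, universe))
  expect_equal(as.numeric(auc3), 0.5)
})

test_that("loo_auc equals brute-force trapezoid ROC integration (property)", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      genes <- sprintf("g%02d", 1:20)
      idx <- t(utils::combn(genes, 2))
      keep <- runif(nrow(idx)) < 0.3
      net <- scored_network(tibble::tibble(
        gene_a = idx[keep, 1], gene_b = idx[keep, 2],
        lls = runif(sum(keep), 0.1, 4), evidence = "X"))
      members <- sample(network_genes(net), 4)
      got <- suppressWarnings(loo_auc(net, members, genes))
      per <- attr(got, "per_member")

      adj <- rbind(
        data.frame(from = net$gene_a, to = net$gene_b, w = net$lls),
        data.frame(from = net$gene_b, to = net$gene_a, w = net$lls))
      oracle <- vapply(members, function(g) {
        rest <- setdiff(members, g)
        cand <- setdiff(genes, rest)
        s <- vapply(cand, function(x)
          sum(adj$w[adj$from == x & adj$to %in% rest]), 0)
        trapezoid_auc(s[cand == g], s[cand != g])
      }, 0)
      expect_equal(per$auc, unname(oracle), tolerance = 1e-12)
      expect_equal(as.numeric(got), mean(oracle), tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under positive rescaling of edge weights", {
  # candidate scores are weight SUMS, so invariance holds for order-preserving
  # linear maps of the weights (a general monotone warp can reorder sums)
  withr::with_seed(73, {
    genes <- sprintf("g%02d", 1:15)
    idx <- t(utils::combn(genes, 2))
    keep <- runif(nrow(idx)) < 0.4
    base <- tibble::tibble(gene_a = idx[keep, 1], gene_b = idx[keep, 2],
                           lls = runif(sum(keep), 0.5, 3), evidence = "X")
    members <- c("g01", "g02", "g03")
    a1 <- loo_auc(scored_network(base), members)
    scaled <- dplyr::mutate(base, lls = 2.5 * lls)
    a2 <- loo_auc(scored_network(scaled), members)
    expect_equal(as.numeric(a1), as.numeric(a2))
  })
})

test_that("true module structure beats weight-shuffled networks in top-bin accuracy", {
  wins <- vapply(1:40, function(r) {
    modules <- make_modules(4, 6)
    net <- module_network(modules, genes = c(unlist(modules), sprintf("bg%02d", 1:20)),
                          p_within = 0.8, p_between = 0.03, seed = r)
    ph_mat <- phenotype_fixture(modules, n_conditions = 8,
                                genes = network_genes(net),
                                defect_rate_in = 1, defect_rate_out = 0, seed = r)
    ph <- phenotypes_from_scores(ph_mat)
    shuffled <- withr::with_seed(1000 + r, {
      s <- tibble::as_tibble(net)
      s$lls <- sample(s$lls)
      scored_network(s)
    })
    curve_t <- accuracy_coverage_curve(net, ph, bin_size = 30,
                                       total_coding_genes = 44)
    curve_s <- accuracy_coverage_curve(shuffled, ph, bin_size = 30,
                                       total_coding_genes = 44)
    isTRUE(curve_t$accuracy[1] > curve_s$accuracy[1])
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("paired AUC comparison reproduces exact signed-rank tails", {
  a <- c(0.8, 0.7, 0.9, 0.6, 0.75, 0.85, 0.65, 0.7, 0.8, 0.9)

  # identical vectors -> p = 1 with a warning
  expect_warning(same <- compare_auc_sets(a, a), "zero")
  expect_equal(same$p_value, 1)

  # constant +0.1 shift, n = 10: exact two-sided tail = 2/2^10
  shifted <- compare_auc_sets(a + 0.1, a)
  expect_equal(shifted$p_value, 2 / 1024, tolerance = 1e-12)
  expect_gt(shifted$effect, 0)

  # swapping the inputs preserves p and flips the effect sign
  swapped <- compare_auc_sets(a, a + 0.1)
  expect_equal(swapped$p_value, shifted$p_value, tolerance = 1e-12)
  expect_equal(swapped$effect, -shifted$effect)

  # enumeration agrees with stats::wilcox.test when magnitudes are untied
  withr::with_seed(79, {
    d <- c(0.11, -0.03, 0.07, 0.2, -0.12, 0.05, 0.09, -0.01)
    ours <- compare_auc_sets(d, rep(0, 8))
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  })
})
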