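make_index <- function(n_articles, arts_a, arts_b) {
  tibble::tibble(
    article = c(arts_a, arts_b),
    gene = c(rep("a", length(arts_a)), rep("b", length(arts_b)))
  )
}

test_that("cocitation p-values match the closed forms", {
  # N=10, m=2, n=2, k=2 -> C(2,2)C(8,0)/C(10,2) = 1/45
  idx <- make_index(10, c(1, 2), c(1, 2))
  expect_equal(cocitation_pvalue(idx, "a", "b", n_articles = 10)$p, 1 / 45)
  # k=1 -> 17/45 by tail summation
  idx <- make_index(10, c(1, 2), c(1, 3))
  expect_equal(cocitation_pvalue(idx, "a", "b", n_articles = 10)$p, 17 / 45)
  # k=0 -> p = 1
  idx <- make_index(10, c(1, 2), c(3, 4))
  expect_equal(cocitation_pvalue(idx, "a", "b", n_articles = 10)$p, 1)
  # unindexed gene -> no score
  expect_true(is.na(cocitation_pvalue(idx, "a", "zzz", n_articles = 10)$p))
})

test_that("cocitation upper tail equals exhaustive enumeration for N <= 12", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      N <- sample(4:12, 1)
      m <- sample(1:(N - 1), 1)
      n <- sample(1:(N - 1), 1)
      arts_a <- sample(N, m)
      arts_b <- sample(N, n)
      k <- length(intersect(arts_a, arts_b))
      idx <- make_index(N, arts_a, arts_b)
      got <- cocitation_pvalue(idx, "a", "b", n_articles = N)$p
      # oracle: enumerate every placement of gene b's articles
      placements <- utils::combn(N, n)
      overlaps <- apply(placements, 2, function(s) length(intersect(s, arts_a)))
      expect_equal(got, mean(overlaps >= k), tolerance = 1e-12)
    }
  })
})

test_that("cocitation_linkset agrees with the per-pair scorer", {
  withr::with_seed(43, {
    idx <- tibble::tibble(
      article = sample(20, 60, replace = TRUE),
      gene = sample(c("a", "b", "c", "d"), 60, replace = TRUE)
    )
    links <- cocitation_linkset(idx, n_articles = 25)
    expect_gt(nrow(links), 0)
    for (i in seq_len(nrow(links))) {
      single <- cocitation_pvalue(idx, links$gene_a[i], links$gene_b[i],
                                  n_articles = 25)
      expect_equal(links$score[i], single$score, tolerance = 1e-12)
    }
  })
})

test_that("coexpression scoring follows the Pearson formula with sample gates", {
  mat <- tibble::tibble(gene = c("u", "v", "w", "z"),
                        !!!setNames(as.data.frame(rbind(
                          1:9, 1:9, -(1:9), rep(1, 9))), paste0("s", 1:9)))
  expect_equal(coexpression_pcc(mat, "u", "v"), 1)
  expect_equal(coexpression_pcc(mat, "u", "w"), -1)
  expect_true(is.na(coexpression_pcc(mat, "u", "z")))  # zero variance

  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 90)
  mat2 <- tibble::tibble(gene = c("x", "y"),
                         !!!setNames(as.data.frame(rbind(x, y)), paste0("s", 1:9)))
  textbook <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(coexpression_pcc(mat2, "x", "y"), textbook, tolerance = 1e-12)

  # too few shared samples -> unscored
  expect_true(is.na(coexpression_pcc(mat2[, 1:6], "x", "y")))
  expect_error(coexpression_linkset(mat2[, 1:6]), "samples")
})

test_that("domain WMI sums rarity bits over shared domains", {
  dom <- tibble::tibble(
    protein = c("p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8",
                "p1", "p2", "p3", "p4"),
    domain = c(rep("D_rare", 2), rep("D_other", 6), rep("D_half", 4))
  )
  # shared domain carried by 2 of 8 proteins: -log2(1/4) = 2 bits
  expect_equal(domain_wmi(dom, "p1", "p2"), 2 + 1)  # D_rare (2) + D_half (1)
  expect_equal(domain_wmi(dom, "p3", "p4"), -log2(6 / 8) + 1)
  expect_equal(domain_wmi(dom, "p5", "p6"), -log2(6 / 8))
  # no shared domain -> 0
  expect_equal(domain_wmi(dom, "p1", "p5"), 0)

  # adding a shared domain of frequency 1/2 raises the score by exactly 1 bit
  before <- domain_wmi(dom[dom$domain != "D_half", ], "p1", "p2",
                       proteome_size = 8)
  after <- domain_wmi(dom, "p1", "p2", proteome_size = 8)
  expect_equal(after - before, 1)
})

test_that("domain WMI grows when a shared domain gets rarer", {
  # dropping a third carrier of the shared domain makes it rarer among the
  # remaining proteome, so the pair's score can only grow
  dom <- tibble::tibble(
    protein = c("p1", "p2", "p3", "p4"),
    domain = c("D1", "D1", "D1", "D2")
  )
  with_p3 <- domain_wmi(dom, "p1", "p2")
  without_p3 <- domain_wmi(dom[dom$protein != "p3", ], "p1", "p2")
  expect_gte(without_p3, with_p3)

  links <- domain_linkset(dom)
  expect_equal(nrow(links), 3)  # the three D1 carrier pairs
  expect_equal(links$score[links$gene_a == "p1" & links$gene_b == "p2"],
               domain_wmi(dom, "p1", "p2"))
})

test_that("profile MI has the closed-form value for identical balanced binary profiles", {
  prof <- tibble::tibble(gene = c("a", "b"),
                         !!!setNames(as.data.frame(rbind(
                           rep(c(0, 1), each = 5), rep(c(0, 1), each = 5))),
                           paste0("G", 1:10)))
  expect_equal(phyloprofile_mi(prof, "a", "b", k = 2), 1)  # 1 bit

  # symmetry on random profiles
  withr::with_seed(47, {
    r <- tibble::tibble(gene = c("a", "b"),
                        !!!setNames(as.data.frame(matrix(runif(40), 2)),
                                    paste0("G", 1:20)))
    expect_equal(phyloprofile_mi(r, "a", "b"), phyloprofile_mi(r, "b", "a"))
  })

  # constant profile degenerates to 0 with a warning
  flat <- tibble::tibble(gene = c("a", "b"),
                         !!!setNames(as.data.frame(rbind(rep(1, 10),
                                                         runif(10))),
                                     paste0("G", 1:10)))
  expect_warning(expect_equal(phyloprofile_mi(flat, "a", "b"), 0), "degenerate")
})

test_that("independent random profiles carry almost no mutual information", {
  withr::with_seed(53, {
    prof <- tibble::tibble(gene = c("a", "b"),
                           !!!setNames(as.data.frame(matrix(runif(2e4), 2)),
                                       paste0("G", 1:1e4)))
    expect_lt(phyloprofile_mi(prof, "a", "b", k = 4), 0.01)
  })
})

test_that("MI is invariant under bin relabeling and taxon partition splits link sets", {
  bx <- rep(1:4, each = 5)
  by <- rep(c(2, 4, 1, 3), each = 5)
  relabel <- c(3, 1, 4, 2)
  expect_equal(cofnet:::mi_bits(bx, by), cofnet:::mi_bits(relabel[bx], by))

  withr::with_seed(59, {
    prof <- tibble::tibble(gene = c("a", "b", "c"),
                           !!!setNames(as.data.frame(matrix(runif(60), 3)),
                                       paste0("G", 1:20)))
    doms <- setNames(rep(c("Archaea", "Bacteria"), each = 10), paste0("G", 1:20))
    parts <- phyloprofile_linkset(prof, genome_domains = doms)
    expect_named(parts, c("Archaea", "Bacteria"))
    expect_equal(attr(parts$Archaea, "evidence_code"), "PG_Archaea")
  })
})

make_context <- function() {
  # three genomes; genes a and b adjacent in g1/g2, far apart in g3
  tibble::tibble(
    genome = rep(c("g1", "g2", "g3"), each = 4),
    replicon = c(rep("c1", 4), rep("c1", 4), "c1", "c1", "c1", "p1"),
    slot = c(1:4, 1:4, 1:3, 1),
    start = c(0, 150, 1000, 2000, 0, 250, 1000, 2000, 0, 5000, 9000, 0),
    end = c(100, 250, 1100, 2100, 200, 350, 1100, 2100, 100, 5100, 9100, 100),
    gene = c("a", "b", "x", "y", "a", "b", "x", "y", "a", "x", "y", "b")
  )
}

test_that("distance-based neighborhood scores the median intergenic gap", {
  ctx <- make_context()
  # distances: 50 (g1), 50 (g2), cap (different replicon in g3) -> median 50
  expect_equal(gn_distance_score(ctx, "a", "b"), -50)
  # co-presence below the genome floor -> no score
  expect_true(is.na(gn_distance_score(ctx, "a", "b", min_genomes = 4)))
  expect_true(is.na(gn_distance_score(ctx, "a", "zzz")))

  # explicit median enumeration with a cap entry
  ctx2 <- ctx
  ctx2$start[ctx2$genome == "g2" & ctx2$gene == "b"] <- 300
  expect_equal(gn_distance_score(ctx2, "a", "b"),
               -stats::median(c(50, 100, 1e6)))
})

test_that("probability-based neighborhood matches the binomial tail", {
  # two genomes, 3 slots each -> q = min(1, 2/2) = 1 is degenerate; use 5 slots
  ctx <- tibble::tibble(
    genome = rep(c("g1", "g2"), each = 5),
    replicon = "c1",
    slot = rep(1:5, 2),
    start = rep(seq(0, 4000, by = 1000), 2),
    end = rep(seq(100, 4100, by = 1000), 2),
    gene = c("a", "b", "x", "y", "z", "a", "b", "x", "y", "z")
  )
  # q = 2*1/4 = 0.5 per genome; neighbors in both of G=2 -> p = 0.25
  got <- gn_probability_score(ctx, "a", "b", window = 1, min_genomes = 2)
  expect_equal(got, -log10(0.25))
  # neighbor in 0 of G -> score 0
  expect_equal(gn_probability_score(ctx, "a", "z", window = 1, min_genomes = 2), 0)

  # tail monotone in the neighbor count at fixed G, q
  tails <- vapply(0:4, function(x)
    if (x == 0) 0 else -log10(stats::pbinom(x - 1, 4, 0.3, lower.tail = FALSE)),
    0)
  expect_true(all(diff(tails) >= 0))
})

test_that("PPI edge lists become unit-score single-bin evidence", {
  edges <- pairs_tbl(c("a", "b", "c", "d"), c("b", "c", "d", "d"))
  expect_warning(links <- ppi_to_linkset(edges, "HT"), "self-pair")
  expect_equal(nrow(links), 3)
  expect_true(all(links$score == 1))
  expect_equal(attr(links, "evidence_code"), "HT")

  # duplicate edge across two sources stays in both per-source sets
  lc <- ppi_to_linkset(pairs_tbl("a", "b"), "LC")
  expect_equal(nrow(lc), 1)
})

test_that("consistent gene relabeling leaves every scorer's output unchanged", {
  relabel <- function(x) chartr("abcd", "wxyz", x)
  withr::with_seed(61, {
    idx <- tibble::tibble(article = sample(10, 30, replace = TRUE),
                          gene = sample(letters[1:4], 30, replace = TRUE))
    p1 <- cocitation_pvalue(idx, "a", "b", n_articles = 12)$p
    idx2 <- dplyr::mutate(idx, gene = relabel(gene))
    expect_equal(cocitation_pvalue(idx2, "w", "x", n_articles = 12)$p, p1)

    dom <- tibble::tibble(protein = sample(letters[1:4], 12, replace = TRUE),
                          domain = sample(c("D1", "D2", "D3"), 12, replace = TRUE))
    expect_equal(domain_wmi(dplyr::mutate(dom, protein = relabel(protein)),
                            "w", "x"),
                 domain_wmi(dom, "a", "b"))

    prof <- tibble::tibble(gene = letters[1:4],
                           !!!setNames(as.data.frame(matrix(runif(48), 4)),
                                       paste0("G", 1:12)))
    prof2 <- dplyr::mutate(prof, gene = relabel(gene))
    expect_equal(phyloprofile_mi(prof2, "w", "x"), phyloprofile_mi(prof, "a", "b"))
  })
})
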