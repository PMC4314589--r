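#' Seeded synthetic inputs for every pipeline stage
#'
#' The generator emulates the statistical structure of each input class —
#' annotation tables with an exact target count of annotation-sharing
#' pairs, evidence scores drawn from separated positive/negative
#' distributions, knockout growth-score matrices with planted gene
#' modules — so the whole construction/assessment/prediction pipeline can
#' be exercised end to end without external data. One integer seed drives
#' everything; sub-generators derive their streams from the seed plus a
#' stage name, so adding a stage never perturbs another stage's draws.
#'
#' @param seed Integer root seed.
#' @param stage Stage name (string).
#' @return `derive_seed()` returns a deterministic 31-bit integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 17
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 65521) * 32749 + h) %% 2147483647L
}

#' @rdname derive_seed
#' @param n_genes Number of genes in the annotated universe (gene ids are
#'   zero-padded `g0001`, ...).
#' @param target_positive_pairs Exact number of annotation-sharing pairs
#'   the fixture must produce.
#' @return `annotation_fixture()` returns a `cofnet_annotation` of disjoint
#'   clique terms whose within-term pair counts sum exactly to
#'   `target_positive_pairs` (greedy largest `choose(k,2) <= remainder`),
#'   with every remaining gene in a singleton term so all `n_genes` are
#'   annotated. When disjoint cliques cannot reach the target with the
#'   genes available, overlapping 2-cliques (sharing one gene) supply the
#'   remaining pairs.
#' @export
annotation_fixture <- function(n_genes, target_positive_pairs) {
  if (target_positive_pairs > choose(n_genes, 2)) {
    abort(sprintf("target %d exceeds choose(%d, 2)", target_positive_pairs, n_genes))
  }
  genes <- sprintf("g%0*d", max(4, nchar(n_genes)), seq_len(n_genes))
  remaining <- target_positive_pairs
  free <- genes
  sizes <- integer()
  members <- list()
  while (remaining > 0 && length(free) >= 2) {
    k <- max(2, floor((1 + sqrt(1 + 8 * remaining)) / 2))  # choose(k,2) <= remaining
    while (choose(k, 2) > remaining) k <- k - 1
    if (k < 2) break
    k <- min(k, length(free))
    sizes <- c(sizes, k)
    members <- c(members, list(free[seq_len(k)]))
    free <- free[-seq_len(k)]
    remaining <- remaining - choose(k, 2)
  }
  if (remaining > 0) {
    # not enough fresh genes for disjoint cliques: add 2-gene terms pairing
    # genes of different existing terms (cross-clique pairs are all new)
    existing <- members
    donors <- genes
    extra <- list()
    for (i in seq_along(donors)) {
      for (j in seq_along(donors)) {
        if (remaining == 0) break
        if (i >= j) next
        same_term <- any(vapply(existing, function(m)
          all(c(donors[i], donors[j]) %in% m), TRUE))
        dup <- any(vapply(extra, function(m)
          setequal(m, c(donors[i], donors[j])), TRUE))
        if (!same_term && !dup) {
          extra <- c(extra, list(c(donors[i], donors[j])))
          remaining <- remaining - 1
        }
      }
      if (remaining == 0) break
    }
    if (remaining > 0) abort("infeasible target for the available gene count")
    members <- c(members, extra)
    sizes <- c(sizes, rep(2L, length(extra)))
  }
  members <- c(members, as.list(free))  # singletons keep all genes annotated
  annotation_table(tibble::tibble(
    term = sprintf("T%04d", seq_along(members)),
    source = "synthetic",
    evidence = rep(list("IDA"), length(members)),
    superpathway = FALSE,
    genes = members
  ))
}

# Draw n values from a named distribution spec: list(name, ...params).
draw_dist <- function(spec, n) {
  switch(spec$name,
    normal = rnorm(n, mean = spec$mean %||% 0, sd = spec$sd %||% 1),
    exponential = rexp(n, rate = spec$rate %||% 1),
    uniform = runif(n, min = spec$min %||% 0, max = spec$max %||% 1),
    abort(sprintf("unknown distribution '%s'", spec$name))
  )
}

#' @rdname derive_seed
#' @param gold A `cofnet_gold`.
#' @param pos_dist,neg_dist Raw-score distributions for gold positives and
#'   negatives: `list(name = "normal"|"exponential"|"uniform", ...)` with
#'   the usual parameters (`mean`, `sd`, `rate`, `min`, `max`).
#' @param coverage Fraction of each gold class to score: a scalar or a
#'   named vector `c(pos = , neg = )`. Negatives are sampled lazily by
#'   unranking pair indices, never materializing the quadratic set.
#' @param evidence_code Label for the generated link set.
#' @return `evidence_fixture()` returns a `cofnet_links`.
#' @export
evidence_fixture <- function(gold, pos_dist = list(name = "normal", mean = 2, sd = 1),
                             neg_dist = list(name = "normal", mean = 0, sd = 1),
                             coverage = 1, evidence_code = "CX", seed = 1) {
  if (length(coverage) == 1) coverage <- c(pos = coverage, neg = coverage)
  stopifnot(all(coverage >= 0), all(coverage <= 1))
  withr::with_seed(derive_seed(seed, paste0("evidence_", evidence_code)), {
    n_pos <- round(coverage[["pos"]] * gold$n_positive)
    pos <- gold$positives[sample(gold$n_positive, n_pos), , drop = FALSE]

    n_neg <- round(coverage[["neg"]] * gold$n_negative)
    genes <- gold$annotated_genes
    n <- length(genes)
    pos_keys <- pair_key(gold$positives$gene_a, gold$positives$gene_b)
    neg <- tibble::tibble(gene_a = character(), gene_b = character())
    if (n_neg > 0) {
      got <- character(0)
      while (length(got) < n_neg) {
        t <- sample(choose(n, 2), min(choose(n, 2), 2 * (n_neg - length(got)) + 10))
        ij <- unrank_pair(t, n)
        cand <- pair_key(genes[ij[, "i"]], genes[ij[, "j"]])
        cand <- setdiff(unique(cand), c(pos_keys, got))
        got <- c(got, cand)
      }
      got <- got[seq_len(n_neg)]
      parts <- strsplit(got, "\x1f", fixed = TRUE)
      neg <- tibble::tibble(gene_a = vapply(parts, `[`, "", 1),
                            gene_b = vapply(parts, `[`, "", 2))
    }
    tab <- dplyr::bind_rows(
      dplyr::mutate(pos, score = draw_dist(pos_dist, nrow(pos))),
      dplyr::mutate(neg, score = draw_dist(neg_dist, nrow(neg)))
    )
    link_set(tab, evidence_code)
  })
}

#' @rdname derive_seed
#' @param modules Named list of gene vectors: the planted cofunctional
#'   modules.
#' @param genes All genes the matrix should cover (defaults to the module
#'   genes).
#' @param n_conditions Number of stress conditions; conditions are assigned
#'   to modules round-robin.
#' @param defect_rate_in Probability a module gene shows a growth defect
#'   (score below −4) under its module's conditions.
#' @param defect_rate_out Probability any other gene-condition cell shows a
#'   defect.
#' @param threshold Growth-defect boundary the fixture plants scores
#'   around (default −4).
#' @return `phenotype_fixture()` returns a wide tibble (first column
#'   `gene`) of growth scores: defect cells fall strictly below the
#'   threshold (`threshold - |Exp(1)| - 0.1`), normal cells are standard
#'   normal.
#' @export
phenotype_fixture <- function(modules, n_conditions, genes = NULL,
                              defect_rate_in = 0.9, defect_rate_out = 0.05,
                              threshold = -4, seed = 1) {
  stopifnot(defect_rate_in >= 0, defect_rate_in <= 1,
            defect_rate_out >= 0, defect_rate_out <= 1)
  genes <- sort(unique(c(genes %||% character(), unlist(modules))))
  conds <- sprintf("cond%03d", seq_len(n_conditions))
  if (n_conditions == 0) {
    return(tibble::tibble(gene = genes))
  }
  cond_module <- if (length(modules)) {
    rep(seq_along(modules), length.out = n_conditions)
  } else integer(n_conditions)
  withr::with_seed(derive_seed(seed, "phenotype"), {
    mat <- matrix(rnorm(length(genes) * n_conditions), nrow = length(genes),
                  dimnames = list(genes, conds))
    for (j in seq_len(n_conditions)) {
      in_module <- if (cond_module[j] > 0) {
        genes %in% modules[[cond_module[j]]]
      } else rep(FALSE, length(genes))
      rate <- ifelse(in_module, defect_rate_in, defect_rate_out)
      defect <- runif(length(genes)) < rate
      mat[defect, j] <- threshold - 0.1 - rexp(sum(defect))
    }
    dplyr::bind_cols(tibble::tibble(gene = genes),
                     tibble::as_tibble(mat))
  })
}

#' @rdname derive_seed
#' @param p_within,p_between Edge probabilities inside and outside planted
#'   modules (for `module_network()`).
#' @param lls_within,lls_between Edge-weight distributions (see `pos_dist`).
#' @return `module_network()` returns a `cofnet_network` with dense
#'   high-LLS edges inside each planted module over a sparse background.
#' @export
module_network <- function(modules, genes = NULL, p_within = 0.8,
                           p_between = 0.01,
                           lls_within = list(name = "normal", mean = 3, sd = 0.5),
                           lls_between = list(name = "exponential", rate = 2),
                           seed = 1) {
  genes <- sort(unique(c(genes %||% character(), unlist(modules))))
  n <- length(genes)
  stopifnot(n >= 2)
  withr::with_seed(derive_seed(seed, "module_network"), {
    idx <- utils::combn(n, 2)
    a <- genes[idx[1, ]]; b <- genes[idx[2, ]]
    within <- rep(FALSE, ncol(idx))
    for (m in modules) within <- within | (a %in% m & b %in% m)
    keep <- runif(ncol(idx)) < ifelse(within, p_within, p_between)
    w <- ifelse(within[keep],
                draw_dist(lls_within, sum(keep)),
                draw_dist(lls_between, sum(keep)))
    scored_network(tibble::tibble(gene_a = a[keep], gene_b = b[keep],
                                  lls = pmax(w, 1e-6), evidence = "SIM"))
  })
}
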