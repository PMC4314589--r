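#' Phenotype assignment from a knockout growth-score matrix
#'
#' A gene is associated with a stress condition when its knockout growth
#' score falls strictly below the threshold (default −4, the conventional
#' growth-defect cutoff). Genes with no phenotype are dropped.
#'
#' @param scores Tibble with first column `gene` and one numeric column per
#'   condition (as read by [read_matrix_tsv()]).
#' @param threshold Growth-defect cutoff; strict `<`.
#' @return A tibble (`gene`, `condition`) of class `cofnet_phenotypes` with
#'   the threshold recorded as an attribute.
#' @export
phenotypes_from_scores <- function(scores, threshold = -4) {
  scores <- tibble::as_tibble(scores)
  stopifnot(names(scores)[1] == "gene")
  long <- tidyr::pivot_longer(scores, -"gene", names_to = "condition",
                              values_to = "score")
  out <- long |>
    dplyr::filter(.data$score < threshold) |>
    dplyr::select("gene", "condition") |>
    dplyr::arrange(.data$gene, .data$condition)
  attr(out, "threshold") <- threshold
  class(out) <- c("cofnet_phenotypes", class(tibble::tibble()))
  out
}

#' @rdname phenotypes_from_scores
#' @param ph A `cofnet_phenotypes`.
#' @return `phenotype_sets()` returns a named list of member-gene vectors,
#'   one per condition (conditions with < 2 members dropped).
#' @export
phenotype_sets <- function(ph) {
  sets <- split(ph$gene, ph$condition)
  sets[lengths(sets) >= 2]
}

# Shared engine for cumulative accuracy-vs-coverage curves. Links are
# sorted by descending weight (ties by pair order); at every cumulated
# prefix of bin_size, 2*bin_size, ... links (plus the final partial
# prefix), accuracy is the percentage of evaluable pairs that "share",
# coverage the percentage of total_genes seen so far.
accuracy_coverage_points <- function(net, share_fun, evaluable_fun,
                                     bin_size, total_genes) {
  stopifnot(nrow(net) > 0, bin_size >= 1, total_genes > 0)
  net <- dplyr::arrange(tibble::as_tibble(net), dplyr::desc(.data$lls),
                        .data$gene_a, .data$gene_b)
  n <- nrow(net)
  evaluable <- evaluable_fun(net$gene_a, net$gene_b)
  shares <- share_fun(net$gene_a, net$gene_b) & evaluable

  genes_seq <- c(rbind(net$gene_a, net$gene_b))      # interleaved a1,b1,a2,b2,...
  new_gene <- !duplicated(genes_seq)
  genes_per_link <- new_gene[c(TRUE, FALSE)] + new_gene[c(FALSE, TRUE)]

  cum_eval <- cumsum(evaluable)
  cum_share <- cumsum(shares)
  cum_genes <- cumsum(genes_per_link)

  ends <- unique(c(seq(bin_size, n, by = bin_size), n))
  tibble::tibble(
    bin = seq_along(ends),
    n_links = ends,
    n_genes = cum_genes[ends],
    coverage = 100 * cum_genes[ends] / total_genes,
    n_evaluable = cum_eval[ends],
    accuracy = ifelse(cum_eval[ends] > 0,
                      100 * cum_share[ends] / cum_eval[ends], NA_real_)
  )
}

#' Cumulative accuracy-vs-coverage curve of a network
#'
#' Links are ranked by edge score and walked in successive bins; at each
#' cumulated prefix the curve records the percentage of evaluable pairs
#' (both endpoints phenotype-annotated) sharing at least one phenotype
#' (accuracy) against the percentage of the coding genome covered by the
#' cumulated genes (coverage). A good network front-loads cofunctional
#' pairs, so accuracy starts high and decays toward the genome-wide
#' baseline as coverage grows.
#'
#' @param net A `cofnet_network`.
#' @param ph A `cofnet_phenotypes` (see [phenotypes_from_scores()]).
#' @param bin_size Gene pairs per bin (default 1000).
#' @param total_coding_genes Size of the coding genome used for coverage.
#' @return A `cofnet_acc_cov` tibble with columns `bin`, `n_links`,
#'   `n_genes`, `coverage`, `n_evaluable`, `accuracy`. Prefixes with no
#'   evaluable pair carry `NA` accuracy.
#' @export
accuracy_coverage_curve <- function(net, ph, bin_size = 1000,
                                    total_coding_genes) {
  stopifnot(inherits(net, "cofnet_network"), inherits(ph, "cofnet_phenotypes"))
  sets <- split(ph$condition, ph$gene)
  share_fun <- function(a, b) {
    purrr::map2_lgl(sets[a], sets[b], function(x, y) {
      !is.null(x) && !is.null(y) && length(intersect(x, y)) > 0
    })
  }
  evaluable_fun <- function(a, b) a %in% names(sets) & b %in% names(sets)
  out <- accuracy_coverage_points(net, share_fun, evaluable_fun,
                                  bin_size, total_coding_genes)
  class(out) <- c("cofnet_acc_cov", class(tibble::tibble()))
  out
}

#' @rdname accuracy_coverage_curve
#' @param object A `cofnet_acc_cov` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.cofnet_acc_cov <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$accuracy), ],
                  ggplot2::aes(x = .data$coverage, y = .data$accuracy)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "coverage of coding genome (%)",
                  y = "pairs sharing a phenotype (%)",
                  title = "Cumulative accuracy vs coverage") +
    ggplot2::theme_minimal()
}

#' Leave-one-out ROC AUC of a gene set in a network
#'
#' Each member gene is held out in turn and every candidate gene is scored
#' by the sum of its edge weights to the remaining members (guilt by
#' association); the held-out member is the single positive of a ROC
#' analysis over the candidates, and the reported AUC is the mean
#' Mann–Whitney AUC (midrank tie handling) over held-out members. Remaining
#' members are excluded from the candidate negatives — they are known
#' positives of the same phenotype.
#'
#' @param net A `cofnet_network`.
#' @param members Gene set (>= 2 genes) defining the phenotype/pathway.
#' @param universe Candidate universe; defaults to all network genes plus
#'   `members`. Members absent from the network score 0 (a warning notes
#'   how many).
#' @return The AUC in `[0, 1]`, with a per-member tibble in
#'   `attr(, "per_member")`.
#' @export
loo_auc <- function(net, members, universe = NULL) {
  stopifnot(inherits(net, "cofnet_network"))
  members <- unique(as.character(members))
  if (length(members) < 2) abort("need at least 2 member genes")
  genes <- network_genes(net)
  universe <- sort(unique(c(universe %||% genes, members)))
  missing <- setdiff(members, genes)
  if (length(missing)) {
    warn(sprintf("%d member gene(s) not in the network score 0", length(missing)))
  }
  adj <- tibble::tibble(
    from = c(net$gene_a, net$gene_b),
    to = c(net$gene_b, net$gene_a),
    w = rep(net$lls, 2)
  )
  per <- purrr::map_dfr(members, function(g) {
    rest <- setdiff(members, g)
    seed_w <- adj[adj$to %in% rest, , drop = FALSE]
    score <- tapply(seed_w$w, seed_w$from, sum)
    candidates <- setdiff(universe, rest)
    s <- setNames(rep(0, length(candidates)), candidates)
    hit <- intersect(names(score), candidates)
    s[hit] <- score[hit]
    pos <- s[g]
    neg <- s[setdiff(candidates, g)]
    auc <- if (length(neg)) {
      (sum(pos > neg) + 0.5 * sum(pos == neg)) / length(neg)
    } else NA_real_  # no candidate beyond the members themselves
    tibble::tibble(member = g, score = pos, n_candidates = length(candidates),
                   auc = auc)
  })
  out <- mean(per$auc, na.rm = TRUE)
  attr(out, "per_member") <- per
  out
}

#' Compare two paired AUC vectors (Wilcoxon signed-rank)
#'
#' Two-sided signed-rank test on per-phenotype AUC pairs. Zero differences
#' are dropped (signed-rank convention). For n <= 15 informative pairs the
#' p-value is exact, computed by enumerating all sign patterns on the
#' midranks of |differences| (so tied magnitudes are handled exactly);
#' larger samples delegate to [stats::wilcox.test()].
#'
#' @param aucs_a,aucs_b Equal-length numeric vectors paired by phenotype.
#' @return A list `(statistic, effect, p_value, n_nonzero, method)`;
#'   `statistic` is `V`, the positive-rank sum of `aucs_a - aucs_b`, and
#'   `effect = V - E[V]` is the signed deviation from the null expectation
#'   (positive when `aucs_a` tends to exceed `aucs_b`).
#' @export
compare_auc_sets <- function(aucs_a, aucs_b) {
  stopifnot(length(aucs_a) == length(aucs_b))
  d <- aucs_a - aucs_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, effect = 0, p_value = 1, n_nonzero = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 15) {
    # exact null: every sign pattern equally likely; two-sided tail around
    # the expected positive-rank sum sum(r)/2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    dev <- abs(vs - sum(r) / 2)
    p <- mean(dev >= abs(v - sum(r) / 2))
    method <- "exact signed-rank (midrank enumeration)"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, paired = FALSE,
                                              exact = FALSE, correct = TRUE))
    p <- wt$p.value
    method <- "normal approximation (stats::wilcox.test)"
  }
  list(statistic = v, effect = v - sum(r) / 2, p_value = min(1, p),
       n_nonzero = n, method = method)
}
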