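# Shared in-code fixtures; everything is generated at test time.

pairs_tbl <- function(a, b, score = NULL) {
  out <- tibble::tibble(gene_a = a, gene_b = b)
  if (!is.null(score)) out$score <- score
  out
}

# An annotation table of module cliques plus singleton background genes.
module_annotation <- function(modules, n_background = 0, evidence = "IDA") {
  singles <- if (n_background > 0) {
    as.list(sprintf("bg%03d", seq_len(n_background)))
  } else list()
  annotation_table(tibble::tibble(
    term = sprintf("M%03d", seq_along(c(modules, singles))),
    evidence = rep(list(evidence), length(modules) + length(singles)),
    genes = c(modules, singles)
  ))
}

# k disjoint modules of m genes each, ids mod<k>_<i>.
make_modules <- function(k, m) {
  lapply(seq_len(k), function(i) sprintf("m%02d_%02d", i, seq_len(m)))
}

# Deterministic toy network from an explicit edge table.
toy_network <- function(...) {
  scored_network(tibble::tibble(...))
}

# Brute-force ROC AUC by trapezoid integration over all score thresholds;
# independent of the Mann-Whitney path in loo_auc().
trapezoid_auc <- function(pos_scores, neg_scores) {
  thr <- sort(unique(c(pos_scores, neg_scores, -Inf, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), 0)
  # midrank handling: average the step heights at tied thresholds
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}
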