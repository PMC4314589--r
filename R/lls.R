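#' Log-likelihood score from bin counts
#'
#' The LLS of an evidence bin is the natural log of the ratio between the
#' posterior odds of a gold-standard positive given the evidence and the
#' prior odds:
#' `ln[((pos_in_bin + c)/(neg_in_bin + c)) / (pos_total/neg_total)]`.
#' Zero means the bin carries no information; positive means enrichment for
#' cofunctional pairs.
#'
#' @param pos_in_bin,neg_in_bin Gold positive/negative counts in the bin.
#' @param pos_total,neg_total Gold-standard totals (must be > 0).
#' @param pseudocount Additive smoothing `c` applied to both bin counts;
#'   the default 0.5 (Haldane–Anscombe) keeps pure bins finite. With
#'   `pseudocount = 0` a bin with both counts zero is an error.
#' @return LLS in natural-log units (vectorized over bin counts).
#' @examples
#' lls_from_counts(90, 10, 1000, 9000, pseudocount = 0)  # ln 81
#' @export
lls_from_counts <- function(pos_in_bin, neg_in_bin, pos_total, neg_total,
                            pseudocount = 0.5) {
  stopifnot(pos_total > 0, neg_total > 0, all(pos_in_bin >= 0),
            all(neg_in_bin >= 0), pseudocount >= 0)
  if (pseudocount == 0 && any(pos_in_bin + neg_in_bin == 0)) {
    abort("bin with zero gold counts and pseudocount 0: LLS undefined; use a nonzero pseudocount")
  }
  log((pos_in_bin + pseudocount) / (neg_in_bin + pseudocount)) -
    log(pos_total / neg_total)
}

#' Benchmark an evidence link set against the gold standard
#'
#' Links are sorted by raw score under the declared orientation and
#' partitioned into bins holding a fixed number of gold-overlapping pairs
#' each (equal-gold-count binning is robust to skewed score distributions;
#' the last bin absorbs the remainder). Each bin's LLS is computed with
#' [lls_from_counts()]. The model records whether the evidence passes the
#' retention rule: maximum bin LLS > 0 and a positive Spearman correlation
#' (p < 0.05) between bin rank and bin positive fraction.
#'
#' @param links A `cofnet_links` evidence set.
#' @param gold A `cofnet_gold`.
#' @param gold_per_bin Gold pairs per bin (default 100).
#' @param pseudocount Passed to [lls_from_counts()].
#' @param min_gold_positives Minimum gold positives overlapping the evidence;
#'   below this the benchmark fails (returned as a failure object, not an
#'   error, so pipelines can drop weak evidence gracefully).
#' @return A `cofnet_lls_model`: bin table plus totals and the pass flag;
#'   on failure, an object with `passed = FALSE` and a `reason`.
#' @export
benchmark_linkset <- function(links, gold, gold_per_bin = 100,
                              pseudocount = 0.5, min_gold_positives = 10) {
  stopifnot(inherits(links, "cofnet_links"), inherits(gold, "cofnet_gold"))
  hib <- isTRUE(attr(links, "higher_is_better"))
  code <- attr(links, "evidence_code")

  lab <- gold_label(gold, links$gene_a, links$gene_b)
  oriented <- if (hib) links$score else -links$score
  ord <- order(oriented, decreasing = TRUE)
  lab <- lab[ord]
  oriented <- oriented[ord]

  is_gold <- !is.na(lab)
  n_pos_overlap <- sum(lab == "positive", na.rm = TRUE)
  if (n_pos_overlap < min_gold_positives) {
    return(structure(list(
      evidence_code = code, passed = FALSE,
      reason = sprintf("only %d gold positives overlap the evidence (need %d)",
                       n_pos_overlap, min_gold_positives)
    ), class = c("cofnet_lls_failure", "cofnet_lls_model")))
  }

  gold_idx <- which(is_gold)
  n_gold <- length(gold_idx)
  bin_of_gold <- pmin((seq_len(n_gold) - 1) %/% gold_per_bin + 1,
                      max(1, n_gold %/% gold_per_bin))  # last bin absorbs remainder
  n_bins <- max(bin_of_gold)

  bins <- tibble::tibble(
    bin = seq_len(n_bins),
    # oriented-score span of each bin's gold pairs; bin 1 = strongest evidence
    upper = vapply(seq_len(n_bins), function(b)
      max(oriented[gold_idx[bin_of_gold == b]]), 0),
    lower = vapply(seq_len(n_bins), function(b)
      min(oriented[gold_idx[bin_of_gold == b]]), 0),
    n_pos = vapply(seq_len(n_bins), function(b)
      sum(lab[gold_idx[bin_of_gold == b]] == "positive"), 0L),
    n_neg = vapply(seq_len(n_bins), function(b)
      sum(lab[gold_idx[bin_of_gold == b]] == "negative"), 0L)
  )
  bins$lls <- lls_from_counts(bins$n_pos, bins$n_neg,
                              gold$n_positive, gold$n_negative, pseudocount)

  # retention rule: informative top bin plus a monotone enrichment trend
  pos_frac <- bins$n_pos / (bins$n_pos + bins$n_neg)
  trend <- if (n_bins >= 3 && stats::sd(pos_frac) > 0) {
    suppressWarnings(stats::cor.test(-bins$bin, pos_frac, method = "spearman",
                                     alternative = "greater"))
  } else NULL
  trend_rho <- if (is.null(trend)) NA_real_ else unname(trend$estimate)
  trend_p <- if (is.null(trend)) NA_real_ else trend$p.value
  passed <- max(bins$lls) > 0 &&
    (n_bins < 3 || (!is.na(trend_p) && trend_rho > 0 && trend_p < 0.05))

  structure(list(
    evidence_code = code,
    higher_is_better = hib,
    bins = bins,
    n_pos_total = gold$n_positive,
    n_neg_total = gold$n_negative,
    n_gold_overlap = n_gold,
    n_pos_overlap = n_pos_overlap,
    pseudocount = pseudocount,
    trend_rho = trend_rho,
    trend_p = trend_p,
    passed = passed,
    reason = if (passed) NA_character_ else "retention rule not met"
  ), class = "cofnet_lls_model")
}

#' Map raw evidence scores through a benchmarked LLS model
#'
#' Each link receives the (piecewise-constant) LLS of the bin its raw score
#' falls in; links below the minimum-LLS cutoff `T` are dropped. Raw scores
#' outside the modeled range are clamped to the nearest end bin and the
#' clamp count logged.
#'
#' @param links The `cofnet_links` the model orientation is compatible with.
#' @param model A passing `cofnet_lls_model`.
#' @param threshold Minimum LLS `T` for a link to be kept (default 0:
#'   uninformative and anti-correlated evidence is dropped).
#' @return A `cofnet_network` whose provenance is the evidence code.
#' @export
apply_lls <- function(links, model, threshold = 0) {
  stopifnot(inherits(links, "cofnet_links"), inherits(model, "cofnet_lls_model"))
  if (inherits(model, "cofnet_lls_failure") || !length(model$bins$lls)) {
    abort("cannot apply a failed LLS benchmark")
  }
  if (!identical(isTRUE(attr(links, "higher_is_better")),
                 model$higher_is_better)) {
    abort("link-set orientation differs from the benchmarked model")
  }
  oriented <- if (model$higher_is_better) links$score else -links$score
  # bins run from strongest (1) downward; a score falls in the first bin
  # whose lower bound it reaches, scores below every bound clamp to the last
  lower <- model$bins$lower
  n_bins <- nrow(model$bins)
  bin <- pmin((n_bins + 1L) - findInterval(oriented, rev(lower)), n_bins)
  n_clamp <- sum(oriented > model$bins$upper[1]) +
    sum(oriented < model$bins$lower[nrow(model$bins)])
  if (n_clamp > 0) {
    inform(sprintf("%d raw score(s) outside the modeled range clamped to end bins",
                   n_clamp))
  }
  lls <- model$bins$lls[bin]
  keep <- lls >= threshold
  scored_network(tibble::tibble(
    gene_a = links$gene_a[keep], gene_b = links$gene_b[keep],
    lls = lls[keep], evidence = model$evidence_code
  ))
}

#' @export
print.cofnet_lls_model <- function(x, ...) {
  if (inherits(x, "cofnet_lls_failure")) {
    cat(sprintf("# LLS benchmark <%s>: FAILED (%s)\n", x$evidence_code, x$reason))
    return(invisible(x))
  }
  cat(sprintf(
    "# LLS benchmark <%s>: %d bins over %d gold pairs (%d pos); max LLS %.3f; %s\n",
    x$evidence_code, nrow(x$bins), x$n_gold_overlap, x$n_pos_overlap,
    max(x$bins$lls), if (x$passed) "passes" else "does not pass"
  ))
  print(x$bins, ...)
  invisible(x)
}

#' @rdname lls_tidiers
#' @export
tidy.cofnet_lls_model <- function(x, ...) {
  if (inherits(x, "cofnet_lls_failure")) {
    return(tibble::tibble(bin = integer(), upper = numeric(), lower = numeric(),
                          n_pos = integer(), n_neg = integer(), lls = numeric()))
  }
  x$bins
}

#' Tidiers for LLS benchmark models
#'
#' `tidy()` returns the per-bin table (oriented-score span, gold counts,
#' LLS); `glance()` a one-row model summary.
#'
#' @param x A `cofnet_lls_model`.
#' @param ... Unused.
#' @name lls_tidiers
#' @export
glance.cofnet_lls_model <- function(x, ...) {
  if (inherits(x, "cofnet_lls_failure")) {
    return(tibble::tibble(evidence_code = x$evidence_code, n_bins = 0L,
                          n_gold_overlap = 0L, n_pos_overlap = 0L,
                          max_lls = NA_real_, trend_rho = NA_real_,
                          trend_p = NA_real_, passed = FALSE))
  }
  tibble::tibble(
    evidence_code = x$evidence_code, n_bins = nrow(x$bins),
    n_gold_overlap = x$n_gold_overlap, n_pos_overlap = x$n_pos_overlap,
    max_lls = max(x$bins$lls), trend_rho = x$trend_rho, trend_p = x$trend_p,
    passed = x$passed
  )
}

#' @rdname lls_tidiers
#' @param object A `cofnet_lls_model` (for `autoplot`).
#' @export
autoplot.cofnet_lls_model <- function(object, ...) {
  stopifnot(!inherits(object, "cofnet_lls_failure"))
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$bin, y = .data$lls)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "evidence bin (1 = strongest raw score)",
      y = "log-likelihood score (nats)",
      title = sprintf("LLS benchmark: %s", object$evidence_code)
    ) +
    ggplot2::theme_minimal()
}
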