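#' Canonicalize unordered gene pairs
#'
#' Cofunctional links are symmetric, so every unordered pair is stored with
#' `gene_a < gene_b` (lexicographic). Self-pairs are dropped with a warning
#' and duplicate pairs are collapsed, keeping the better score under the
#' declared orientation when a `score` column is present.
#'
#' @param pairs A data frame with character columns `gene_a` and `gene_b`,
#'   optionally a numeric `score` column.
#' @param higher_is_better Orientation of `score`: if `TRUE` (default) larger
#'   scores win when duplicates collapse, otherwise smaller ones.
#' @return A tibble with canonical, deduplicated pairs.
#' @examples
#' canonicalize_pairs(tibble::tibble(gene_a = "g2", gene_b = "g1", score = 0.5))
#' @export
canonicalize_pairs <- function(pairs, higher_is_better = TRUE) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)

  self <- pairs$gene_a == pairs$gene_b
  if (any(self)) {
    warn(sprintf("dropped %d self-pair(s)", sum(self)))
    pairs <- pairs[!self, , drop = FALSE]
  }
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- a
  pairs$gene_b <- b

  if ("score" %in% names(pairs)) {
    pairs <- pairs |>
      dplyr::arrange(if (higher_is_better) dplyr::desc(.data$score) else .data$score) |>
      dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  } else {
    pairs <- dplyr::distinct(pairs) |> dplyr::arrange(.data$gene_a, .data$gene_b)
  }
  pairs
}

# Internal single-string key for an unordered canonical pair.
pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\x1f")

# Unrank pair index t in 1..choose(n, 2) to 1-based (i, j), i < j, in the
# order (1,2),(1,3),...,(1,n),(2,3),...  Vectorized over t.
unrank_pair <- function(t, n) {
  t <- as.numeric(t)
  # solve for i: pairs with first index < i total (i-1)*n - i*(i-1)/2
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * t))
  before <- (i - 1) * n - i * (i - 1) / 2
  j <- i + (t - before)
  cbind(i = as.integer(i), j = as.integer(j))
}
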