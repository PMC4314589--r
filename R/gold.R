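#' Filter annotation terms before gold-standard derivation
#'
#' Three filters guard the gold standard against biased learning: an
#' evidence-code whitelist (annotations inferred electronically are too
#' noisy to train on), an explicit exclusion list for very large terms
#' (by default the five largest transcription-related GO-BP processes,
#' whose thousands of co-member pairs would dominate training), and
#' removal of superpathway composites (which would assert between-pathway
#' associations).
#'
#' @param annot A `cofnet_annotation`.
#' @param evidence Character whitelist of GO evidence codes; a term is kept
#'   if any of its codes is whitelisted. Terms declaring no evidence codes
#'   (e.g. curated pathway databases) always pass. `NULL` disables the
#'   filter.
#' @param excluded_terms Term ids to remove; defaults to none. See
#'   [large_process_terms()] for the conventional exclusion list.
#' @param exclude_superpathways Drop terms flagged `superpathway`.
#' @param max_term_size Optional generic size cutoff (defaults to `Inf`,
#'   i.e. off; exclusion is normally by explicit id list).
#' @return The filtered `cofnet_annotation`.
#' @export
filter_terms <- function(annot, evidence = c("IDA", "IGI", "IMP"),
                         excluded_terms = character(),
                         exclude_superpathways = FALSE,
                         max_term_size = Inf) {
  stopifnot(inherits(annot, "cofnet_annotation"))
  keep <- rep(TRUE, nrow(annot))
  if (!is.null(evidence)) {
    keep <- keep & vapply(annot$evidence, function(e) {
      length(e) == 0 || any(e %in% evidence)
    }, TRUE)
  }
  missing_ids <- setdiff(excluded_terms, annot$term)
  if (length(missing_ids)) {
    warn(sprintf("excluded term id(s) not present: %s",
                 paste(missing_ids, collapse = ", ")))
  }
  keep <- keep & !(annot$term %in% excluded_terms)
  if (exclude_superpathways) keep <- keep & !annot$superpathway
  keep <- keep & annot$n_genes <= max_term_size
  out <- annot[keep, , drop = FALSE]
  class(out) <- class(annot)
  out
}

#' The five largest transcription-related GO-BP terms
#'
#' Conventional exclusion list for gold-standard training: DNA-dependent
#' transcription and its regulation terms, whose very large memberships
#' would bias learning toward a handful of broad processes.
#'
#' @return Character vector of five GO ids.
#' @export
large_process_terms <- function() {
  c("GO:0006351", "GO:0045892", "GO:0006355", "GO:0000160", "GO:0045893")
}

#' Positive gold-standard pairs from an annotation table
#'
#' Pairs of distinct genes that are co-members of at least one term, each
#' unordered pair exactly once.
#'
#' @param annot A (filtered) `cofnet_annotation`.
#' @return Tibble of canonical pairs (`gene_a`, `gene_b`).
#' @export
positives_from_annotation <- function(annot) {
  stopifnot(inherits(annot, "cofnet_annotation"))
  per_term <- lapply(annot$genes, function(g) {
    g <- sort(unique(g))
    if (length(g) < 2) return(NULL)
    idx <- utils::combn(length(g), 2)
    tibble::tibble(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]])
  })
  out <- dplyr::bind_rows(per_term)
  if (!nrow(out)) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  dplyr::distinct(out) |> dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Merge two positive pair sets with overlap bookkeeping
#'
#' @param a,b Tibbles of canonical pairs (`gene_a`, `gene_b`).
#' @return A list with `union` (tibble of pairs), `overlap_count`
#'   (`|a intersect b|`) and `pct_overlap_of_b` (share of `b` already in
#'   `a`, percent, nearest integer).
#' @export
merge_positive_sets <- function(a, b) {
  ka <- pair_key(a$gene_a, a$gene_b)
  kb <- pair_key(b$gene_a, b$gene_b)
  overlap <- sum(kb %in% ka)
  un <- dplyr::distinct(dplyr::bind_rows(a, b)) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  list(
    union = un,
    overlap_count = overlap,
    pct_overlap_of_b = round(100 * overlap / max(1, length(kb)))
  )
}

#' Negative gold-standard pairs
#'
#' Every unordered pair of annotated genes that shares no annotation, i.e.
#' all `choose(n, 2)` pairs over the annotated-gene universe minus the
#' positives. The negative set is quadratic, so by default only its exact
#' count is returned; `materialize = TRUE` enumerates the pairs (use only
#' for small universes).
#'
#' @param annotated A character vector: the annotated-gene universe.
#' @param positives Tibble of canonical positive pairs over `annotated`.
#' @param materialize Return the pairs themselves instead of the count.
#' @return The negative-pair count (double, exact), or a tibble of pairs.
#' @export
negatives_from_annotation <- function(annotated, positives, materialize = FALSE) {
  annotated <- sort(unique(as.character(annotated)))
  ok <- positives$gene_a %in% annotated & positives$gene_b %in% annotated
  if (!all(ok)) {
    abort("positive pair with endpoint outside the annotated-gene universe")
  }
  n <- length(annotated)
  total <- choose(n, 2)
  n_pos <- nrow(dplyr::distinct(positives[c("gene_a", "gene_b")]))
  if (!materialize) return(total - n_pos)
  idx <- utils::combn(n, 2)
  all_pairs <- tibble::tibble(gene_a = annotated[idx[1, ]],
                              gene_b = annotated[idx[2, ]])
  neg <- all_pairs[!pair_key(all_pairs$gene_a, all_pairs$gene_b) %in%
                     pair_key(positives$gene_a, positives$gene_b), , drop = FALSE]
  tibble::as_tibble(neg)
}

#' Assemble a gold standard from an annotation table
#'
#' Derives positives by co-annotation and the (lazy) negative universe over
#' the annotated genes, recording the prior odds `P(L)/P(~L)` used by LLS
#' benchmarking.
#'
#' @param annot A filtered `cofnet_annotation` (see [filter_terms()]).
#' @return A `cofnet_gold` list: `positives` (tibble of pairs),
#'   `annotated_genes`, `n_positive`, `n_negative`, `prior_odds`.
#' @export
gold_standard <- function(annot) {
  pos <- positives_from_annotation(annot)
  genes <- annotated_genes(annot)
  n_neg <- negatives_from_annotation(genes, pos)
  structure(list(
    positives = pos,
    annotated_genes = genes,
    n_positive = nrow(pos),
    n_negative = n_neg,
    prior_odds = nrow(pos) / n_neg
  ), class = "cofnet_gold")
}

#' @export
print.cofnet_gold <- function(x, ...) {
  cat(sprintf(
    "# Gold standard: %d positives, %s negatives over %d annotated genes (prior odds %.3g)\n",
    x$n_positive, format(x$n_negative, big.mark = ","),
    length(x$annotated_genes), x$prior_odds
  ))
  invisible(x)
}

# Label canonical pairs against a gold standard: "positive", "negative"
# (both genes annotated, pair not positive) or NA (not evaluable).
gold_label <- function(gold, gene_a, gene_b) {
  pos <- pair_key(gene_a, gene_b) %in% pair_key(gold$positives$gene_a,
                                                gold$positives$gene_b)
  annotated <- gene_a %in% gold$annotated_genes & gene_b %in% gold$annotated_genes
  dplyr::case_when(pos ~ "positive", annotated ~ "negative",
                   .default = NA_character_)
}
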