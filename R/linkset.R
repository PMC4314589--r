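#' Evidence link sets and scored networks
#'
#' An evidence link set is a tibble of canonical gene pairs with one raw
#' score per pair from a single data source (cocitation, coexpression,
#' domain co-occurrence, ...). A scored network is a tibble of canonical
#' pairs carrying a log-likelihood score (LLS, natural-log units) and the
#' evidence codes that contributed to each edge.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`, `score`.
#' @param evidence_code Label for the data source, conventionally one of
#'   `"CC"`, `"CX"`, `"DC"`, `"GN"`, `"HT"`, `"LC"`, `"PG"`; free labels are
#'   allowed (e.g. one label per coexpression series).
#' @param higher_is_better Does a larger raw score mean stronger evidence?
#' @return `link_set()` returns a `cofnet_links` tibble (columns `gene_a`,
#'   `gene_b`, `score`) with attributes `evidence_code` and
#'   `higher_is_better`.
#' @examples
#' link_set(tibble::tibble(gene_a = "b", gene_b = "a", score = 1), "CC")
#' @export
link_set <- function(pairs, evidence_code, higher_is_better = TRUE) {
  stopifnot(is.character(evidence_code), length(evidence_code) == 1)
  pairs <- canonicalize_pairs(pairs, higher_is_better = higher_is_better)
  stopifnot("score" %in% names(pairs), all(is.finite(pairs$score)))
  out <- pairs[c("gene_a", "gene_b", "score")]
  attr(out, "evidence_code") <- evidence_code
  attr(out, "higher_is_better") <- higher_is_better
  class(out) <- c("cofnet_links", class(tibble::tibble()))
  out
}

#' @rdname link_set
#' @param links For `scored_network()`: data frame with columns `gene_a`,
#'   `gene_b`, `lls` and optionally `evidence` (comma-joined codes).
#' @export
scored_network <- function(links) {
  links <- tibble::as_tibble(links)
  stopifnot(all(c("gene_a", "gene_b", "lls") %in% names(links)))
  if (!"evidence" %in% names(links)) links$evidence <- ""
  links <- canonicalize_pairs(links)
  stopifnot(all(is.finite(links$lls)))
  out <- links[c("gene_a", "gene_b", "lls", "evidence")] |>
    dplyr::arrange(dplyr::desc(.data$lls), .data$gene_a, .data$gene_b)
  class(out) <- c("cofnet_network", class(tibble::tibble()))
  out
}

#' @rdname link_set
#' @param net A `cofnet_network`.
#' @export
network_genes <- function(net) {
  sort(unique(c(net$gene_a, net$gene_b)))
}

#' @export
print.cofnet_links <- function(x, ...) {
  cat(sprintf(
    "# Evidence link set <%s>: %d links, %d genes (%s is better)\n",
    attr(x, "evidence_code"), nrow(x), length(unique(c(x$gene_a, x$gene_b))),
    if (isTRUE(attr(x, "higher_is_better"))) "higher" else "lower"
  ))
  NextMethod()
}

#' @export
print.cofnet_network <- function(x, ...) {
  cat(sprintf(
    "# Scored network: %d links, %d genes, LLS in [%.3g, %.3g]\n",
    nrow(x), length(unique(c(x$gene_a, x$gene_b))),
    if (nrow(x)) min(x$lls) else NA, if (nrow(x)) max(x$lls) else NA
  ))
  NextMethod()
}
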