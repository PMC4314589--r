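#' Prioritize new candidate members of a pathway or phenotype
#'
#' Guilt by association: given query genes known to act in one pathway or
#' to share a phenotype, every non-query network gene is scored by the sum
#' of its edge LLS weights to the query genes it connects to, and the top
#' candidates are returned with their supporting evidence. The internal
#' connectivity of the query set is first summarized as a leave-one-out
#' ROC AUC ([loo_auc()]); a high AUC means the query genes are tightly
#' interconnected, so unconnected genes ranking high are credible new
#' members.
#'
#' @param net A `cofnet_network`.
#' @param query Query gene ids (>= 2 must be present in the network).
#' @param top_k Number of candidates to return (default 100).
#' @return A `cofnet_ranking`: list with `candidates` (tibble: `rank`,
#'   `gene`, `score`, `n_support`, `evidence`), `connectivity_auc`,
#'   `n_query`, `n_found`, `missing`.
#' @export
find_new_members <- function(net, query, top_k = 100) {
  stopifnot(inherits(net, "cofnet_network"))
  query <- unique(as.character(query))
  genes <- network_genes(net)
  found <- intersect(query, genes)
  if (length(found) < 2) {
    abort(sprintf("only %d of %d query genes are in the network; need >= 2",
                  length(found), length(query)))
  }
  auc <- loo_auc(net, found)

  adj <- tibble::tibble(
    from = c(net$gene_a, net$gene_b),
    to = c(net$gene_b, net$gene_a),
    w = rep(net$lls, 2),
    evidence = rep(net$evidence, 2)
  )
  cand <- adj |>
    dplyr::filter(.data$to %in% found, !.data$from %in% query) |>
    dplyr::group_by(gene = .data$from) |>
    dplyr::summarise(
      score = sum(.data$w),
      n_support = dplyr::n(),
      evidence = paste(sort(unique(unlist(strsplit(.data$evidence, ",", fixed = TRUE)))),
                       collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$n_support),
                   .data$gene) |>
    dplyr::slice_head(n = top_k)
  cand$rank <- seq_len(nrow(cand))

  structure(list(
    candidates = cand[c("rank", "gene", "score", "n_support", "evidence")],
    connectivity_auc = as.numeric(auc),
    n_query = length(query),
    n_found = length(found),
    missing = setdiff(query, genes)
  ), class = "cofnet_ranking")
}

#' @export
print.cofnet_ranking <- function(x, ...) {
  cat(sprintf(
    "# Candidate ranking: %d of %d query genes found; connectivity AUC %.3f\n",
    x$n_found, x$n_query, x$connectivity_auc
  ))
  print(x$candidates, ...)
  invisible(x)
}

#' @rdname find_new_members
#' @param x A `cofnet_ranking`.
#' @param ... Unused.
#' @export
tidy.cofnet_ranking <- function(x, ...) x$candidates

#' @rdname find_new_members
#' @export
glance.cofnet_ranking <- function(x, ...) {
  tibble::tibble(connectivity_auc = x$connectivity_auc, n_query = x$n_query,
                 n_found = x$n_found, n_candidates = nrow(x$candidates))
}

#' Infer functions for a gene from its network neighbors
#'
#' Each annotation term is scored by the summed LLS of the query gene's
#' edges to neighbors annotated with that term, after restricting the
#' annotation to reliably evidenced terms (default whitelist: IDA, IMP,
#' IGI, IPI, IEP, TAS — experimental evidence and the literature). Terms
#' are ranked by score, ties broken by smaller term size (more specific
#' first) then term id.
#'
#' @param net A `cofnet_network`.
#' @param gene Query gene id (must be in the network).
#' @param annot A `cofnet_annotation` (e.g. GO-BP terms).
#' @param evidence Evidence-code whitelist applied via [filter_terms()];
#'   `NULL` disables the filter.
#' @param top_k Number of terms to return (default 30).
#' @return A `cofnet_functions` tibble: `rank`, `term`, `score`, `n_genes`
#'   (term size), `n_neighbors`, `neighbors` (comma-joined contributors).
#'   Empty when the gene has no annotated neighbor.
#' @export
infer_functions <- function(net, gene, annot,
                            evidence = c("IDA", "IMP", "IGI", "IPI", "IEP", "TAS"),
                            top_k = 30) {
  stopifnot(inherits(net, "cofnet_network"), inherits(annot, "cofnet_annotation"))
  genes <- network_genes(net)
  if (!gene %in% genes) abort(sprintf("gene '%s' is not in the network", gene))
  annot <- filter_terms(annot, evidence = evidence)

  nb <- tibble::tibble(
    neighbor = c(net$gene_b[net$gene_a == gene], net$gene_a[net$gene_b == gene]),
    w = c(net$lls[net$gene_a == gene], net$lls[net$gene_b == gene])
  )
  empty <- tibble::tibble(rank = integer(), term = character(),
                          score = numeric(), n_genes = integer(),
                          n_neighbors = integer(), neighbors = character())
  class(empty) <- c("cofnet_functions", class(tibble::tibble()))
  if (!nrow(nb)) return(empty)

  term_scores <- purrr::pmap_dfr(
    list(annot$term, annot$genes, annot$n_genes),
    function(term, members, n_genes) {
      hit <- nb[nb$neighbor %in% members, , drop = FALSE]
      if (!nrow(hit)) return(NULL)
      tibble::tibble(term = term, score = sum(hit$w),
                     n_genes = as.integer(n_genes),
                     n_neighbors = nrow(hit),
                     neighbors = paste(sort(unique(hit$neighbor)), collapse = ","))
    }
  )
  if (!nrow(term_scores)) return(empty)
  out <- term_scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$n_genes, .data$term) |>
    dplyr::slice_head(n = top_k)
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  class(out) <- c("cofnet_functions", class(tibble::tibble()))
  out
}

#' Hypergeometric alternative for neighbor-based function scoring
#'
#' Same contract as [infer_functions()], but terms are ranked by
#' enrichment of the gene's neighbors among term members (upper-tail
#' hypergeometric over the network gene universe) instead of by summed
#' edge weight; score is `-log10 p`.
#'
#' @inheritParams infer_functions
#' @export
infer_functions_hyper <- function(net, gene, annot,
                                  evidence = c("IDA", "IMP", "IGI", "IPI", "IEP", "TAS"),
                                  top_k = 30) {
  stopifnot(inherits(net, "cofnet_network"))
  genes <- network_genes(net)
  if (!gene %in% genes) abort(sprintf("gene '%s' is not in the network", gene))
  annot <- filter_terms(annot, evidence = evidence)
  neighbors <- unique(c(net$gene_b[net$gene_a == gene],
                        net$gene_a[net$gene_b == gene]))
  universe <- setdiff(genes, gene)
  empty <- tibble::tibble(rank = integer(), term = character(),
                          score = numeric(), n_genes = integer(),
                          n_neighbors = integer(), neighbors = character())
  class(empty) <- c("cofnet_functions", class(tibble::tibble()))
  if (!length(neighbors)) return(empty)

  rows <- purrr::pmap_dfr(
    list(annot$term, annot$genes, annot$n_genes),
    function(term, members, n_genes) {
      members <- intersect(members, universe)
      k <- length(intersect(members, neighbors))
      if (k == 0) return(NULL)
      p <- stats::phyper(k - 1, length(members),
                         length(universe) - length(members),
                         length(neighbors), lower.tail = FALSE)
      tibble::tibble(term = term, score = -log10(max(p, .Machine$double.xmin)),
                     n_genes = as.integer(n_genes), n_neighbors = k,
                     neighbors = paste(sort(intersect(members, neighbors)),
                                       collapse = ","))
    }
  )
  if (!nrow(rows)) return(empty)
  out <- rows |>
    dplyr::arrange(dplyr::desc(.data$score), .data$n_genes, .data$term) |>
    dplyr::slice_head(n = top_k)
  out <- dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
  class(out) <- c("cofnet_functions", class(tibble::tibble()))
  out
}
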