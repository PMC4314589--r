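#' Weighted-sum integration of one pair's evidence scores
#'
#' Multiple evidence sources supporting the same gene pair are combined as
#' `WS = S0 + sum_{i=1..n} Si / (D * i)` over the LLS values `S >= T`, where
#' `S0` is the best score, `Si` the i-th remaining score in descending
#' order, `D >= 1` a weight factor discounting correlated secondary
#' evidence, and `T` the minimum LLS admitted to the sum. `D = 1` recovers
#' plain rank-discounted addition; `D -> Inf` keeps only the single best
#' evidence.
#'
#' @param scores Numeric LLS values from distinct evidence networks.
#' @param D Weight factor (`>= 1`).
#' @param T Minimum LLS cutoff applied to individual scores before ranking.
#' @return The weighted sum, or `NA_real_` when no score survives `T`
#'   (the pair is then absent from an integrated network).
#' @examples
#' weighted_sum(c(3, 2, 1), D = 1, T = 0)    # 5.5
#' weighted_sum(c(3, 2, 1), D = 2, T = 1.5)  # 4
#' @export
weighted_sum <- function(scores, D = 1, T = 0) {
  stopifnot(is.numeric(scores), D >= 1)
  s <- sort(scores[scores >= T], decreasing = TRUE)
  if (!length(s)) return(NA_real_)
  if (length(s) == 1) return(s)
  s[1] + sum(s[-1] / (D * seq_along(s[-1])))
}

#' Integrate LLS-scored networks into one network
#'
#' Assembles, for every gene pair, the stack of LLS values across the input
#' networks (one value per network; absence contributes nothing), applies
#' [weighted_sum()], and unions the evidence-code provenance. The same
#' machinery serves integration across data types and within one data type
#' (many coexpression series into one CX network, Archaea + Bacteria
#' profile networks into one PG network, two gene-neighborhood variants
#' into one GN network).
#'
#' @param nets List of `cofnet_network` objects. Two networks whose edges
#'   carry the same evidence code must not overlap (pre-merge them first).
#' @param D,T Weighted-sum parameters (see [weighted_sum()]).
#' @param evidence_override Optional single code to stamp on the result
#'   (e.g. `"CX"` after merging per-series networks); default keeps the
#'   per-edge union of contributing codes.
#' @return A `cofnet_network`.
#' @export
integrate_networks <- function(nets, D = 1, T = 0, evidence_override = NULL) {
  stopifnot(length(nets) >= 1)
  purrr::walk(nets, function(n) stopifnot(inherits(n, "cofnet_network")))
  tagged <- purrr::imap(nets, function(n, i) {
    dplyr::mutate(tibble::as_tibble(n), .net = i)
  })
  all_edges <- dplyr::bind_rows(tagged)

  dup <- all_edges |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .data$evidence, .data$.net) |>
    dplyr::count(.data$gene_a, .data$gene_b, .data$evidence) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf(
      "evidence code '%s' appears in multiple networks with overlapping pairs; pre-merge those networks",
      dup$evidence[1]
    ))
  }

  surv <- dplyr::filter(all_edges, .data$lls >= T)
  if (!nrow(surv)) {
    return(scored_network(tibble::tibble(gene_a = character(),
                                         gene_b = character(),
                                         lls = numeric(),
                                         evidence = character())))
  }
  out <- surv |>
    dplyr::arrange(dplyr::desc(.data$lls), .data$evidence) |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(
      lls = {
        s <- .data$lls
        if (length(s) == 1) s else s[1] + sum(s[-1] / (D * seq_along(s[-1])))
      },
      evidence = paste(unique(unlist(strsplit(.data$evidence, ",", fixed = TRUE))),
                       collapse = ","),
      .groups = "drop"
    )
  if (!is.null(evidence_override)) out$evidence <- evidence_override
  scored_network(out)
}

#' Tune the weighted-sum parameters on held-out gold positives
#'
#' Grid search over (D, T): for each candidate the networks are integrated
#' and scored by the area under the cumulative accuracy-vs-coverage curve
#' computed against a held-out half of the gold-standard positives
#' (accuracy = share of evaluable cumulated pairs that are held-out
#' positives; coverage = share of annotated genes cumulated). The split is
#' seeded and reported.
#'
#' @param nets List of `cofnet_network`.
#' @param gold A `cofnet_gold`.
#' @param D_grid,T_grid Candidate values.
#' @param seed Integer seed for the gold split.
#' @param bin_size Links per curve bin (default 100; tuning-scale curves).
#' @return A list `(D, T, area, grid)` with the full grid as a tibble.
#' @export
tune_ws <- function(nets, gold, D_grid = c(1, 2, 4), T_grid = c(0, 0.5, 1),
                    seed = 1, bin_size = 100) {
  stopifnot(length(D_grid) >= 1, length(T_grid) >= 1)
  if (length(D_grid) == 1 && length(T_grid) == 1) {
    warn("degenerate grid: returning the single candidate")
  }
  n_pos <- nrow(gold$positives)
  held <- withr::with_seed(derive_seed(seed, "tune_ws_split"),
                           sample(n_pos, size = floor(n_pos / 2)))
  heldout <- gold$positives[held, , drop = FALSE]

  grid <- tidyr::expand_grid(D = D_grid, T = T_grid)
  grid$area <- purrr::map2_dbl(grid$D, grid$T, function(D, T) {
    net <- integrate_networks(nets, D = D, T = T)
    if (!nrow(net)) return(-Inf)
    acc_cov_area(net, heldout, gold$annotated_genes, bin_size = bin_size)
  })
  best <- which.max(grid$area)
  list(D = grid$D[best], T = grid$T[best], area = grid$area[best],
       seed = seed, grid = grid)
}

# Area under the accuracy-vs-coverage curve against a positive pair set;
# evaluable pairs have both endpoints annotated. Trapezoid over coverage.
acc_cov_area <- function(net, positives, annotated, bin_size = 100) {
  curve <- accuracy_coverage_points(
    net,
    share_fun = function(a, b) pair_key(a, b) %in%
      pair_key(positives$gene_a, positives$gene_b),
    evaluable_fun = function(a, b) a %in% annotated & b %in% annotated,
    bin_size = bin_size, total_genes = length(annotated)
  )
  curve <- curve[!is.na(curve$accuracy), , drop = FALSE]
  if (nrow(curve) < 2) return(if (nrow(curve)) curve$accuracy[1] else -Inf)
  sum(diff(curve$coverage) * (head(curve$accuracy, -1) + curve$accuracy[-1]) / 2)
}
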