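#' Read an evidence edge list from TSV
#'
#' Expects three tab-separated columns (geneA, geneB, score); an optional
#' header line is detected by a non-numeric third field. Pairs are
#' canonicalized (`gene_a < gene_b`), self-pairs are skipped with a logged
#' count, and duplicate pairs collapse to the better score under the
#' declared orientation.
#'
#' @inheritParams link_set
#' @param path Path to the TSV file.
#' @return A `cofnet_links` tibble.
#' @export
read_edge_list <- function(path, evidence_code, higher_is_better = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(link_set(tibble::tibble(gene_a = character(), gene_b = character(),
                                   score = numeric()),
                    evidence_code, higher_is_better))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("malformed edge-list row at line %d of %s (need 3 columns)",
                  bad[1], path))
  }
  first_score <- suppressWarnings(as.numeric(fields[[1]][3]))
  if (is.na(first_score)) fields <- fields[-1]  # header line
  tab <- tibble::tibble(
    gene_a = vapply(fields, `[`, "", 1),
    gene_b = vapply(fields, `[`, "", 2),
    score  = suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  )
  if (anyNA(tab$score)) {
    abort(sprintf("non-numeric score at line %d of %s",
                  which(is.na(tab$score))[1] + ifelse(is.na(first_score), 1, 0),
                  path))
  }
  link_set(tab, evidence_code, higher_is_better)
}

#' Read gene-set annotations (GMT dialect)
#'
#' One term per line: term id, a description field, then member genes, all
#' tab-separated. The description field may carry `key=value` metadata
#' separated by `;` with keys `source` (GO-BP, EcoCyc, MetaCyc, ...),
#' `evidence` (comma-joined GO evidence codes) and `superpathway`
#' (true/false). Terms with no member genes are dropped with a warning;
#' duplicate term ids are an error.
#'
#' @param path Path to a GMT file.
#' @return A `cofnet_annotation` tibble with columns `term`, `source`,
#'   `evidence` (list of character), `superpathway`, `genes` (list of
#'   character) and `n_genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  # a term with zero genes has exactly 2 fields: dropped below, not an error
  hard_bad <- which(lengths(fields) < 2)
  if (length(hard_bad)) {
    abort(sprintf("malformed gene-set row at line %d of %s", hard_bad[1], path))
  }
  if (length(bad)) {
    warn(sprintf("dropped %d empty term(s) in %s", length(bad), path))
    fields <- fields[lengths(fields) >= 3]
  }
  term <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(term)) {
    abort(sprintf("duplicate term id '%s' in %s", term[duplicated(term)][1], path))
  }
  meta <- vapply(fields, `[`, "", 2)
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  parse_meta <- function(m, key) {
    kv <- strsplit(strsplit(m, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    hit <- vapply(kv, function(x) length(x) == 2 && x[1] == key, TRUE)
    if (any(hit)) kv[hit][[1]][2] else NA_character_
  }
  annotation_table(tibble::tibble(
    term = term,
    source = unname(vapply(meta, parse_meta, "", key = "source")),
    evidence = lapply(meta, function(m) {
      e <- parse_meta(m, "evidence")
      if (is.na(e) || !nzchar(e)) character() else strsplit(e, ",", fixed = TRUE)[[1]]
    }),
    superpathway = unname(tolower(vapply(meta, parse_meta, "",
                                         key = "superpathway"))) %in%
      c("true", "1", "yes"),
    genes = genes
  ))
}

#' Construct an annotation table
#'
#' @param terms Data frame with columns `term` and `genes` (list of character
#'   vectors); optional `source`, `evidence` (list of character),
#'   `superpathway` (logical).
#' @return A `cofnet_annotation` tibble.
#' @export
annotation_table <- function(terms) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("term", "genes") %in% names(terms)))
  if (anyDuplicated(terms$term)) {
    abort(sprintf("duplicate term id '%s'", terms$term[duplicated(terms$term)][1]))
  }
  if (!"source" %in% names(terms)) terms$source <- NA_character_
  if (!"evidence" %in% names(terms)) terms$evidence <- list(character())
  if (!"superpathway" %in% names(terms)) terms$superpathway <- FALSE
  terms$genes <- lapply(terms$genes, function(g) unique(as.character(g)))
  terms$n_genes <- lengths(terms$genes)
  out <- terms[c("term", "source", "evidence", "superpathway", "genes", "n_genes")]
  class(out) <- c("cofnet_annotation", class(tibble::tibble()))
  out
}

#' Genes appearing in at least one term
#' @param annot A `cofnet_annotation`.
#' @return Sorted character vector.
#' @export
annotated_genes <- function(annot) sort(unique(unlist(annot$genes)))

#' Write / read a scored network as TSV
#'
#' Four tab-separated columns: geneA, geneB, LLS (natural-log units, full
#' double precision), comma-joined evidence codes. Rows are sorted by
#' descending LLS, ties by pair lexicographic order, so writing is
#' deterministic and write-read round-trips are lossless.
#'
#' @param net A `cofnet_network`.
#' @param path Output path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `cofnet_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "cofnet_network"), all(is.finite(net$lls)))
  net <- dplyr::arrange(net, dplyr::desc(.data$lls), .data$gene_a, .data$gene_b)
  header <- "# cofnet network: geneA\tgeneB\tLLS(natural log)\tevidence"
  body <- sprintf("%s\t%s\t%s\t%s", net$gene_a, net$gene_b,
                  formatC(net$lls, digits = 17, format = "g"), net$evidence)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(scored_network(tibble::tibble(gene_a = character(),
                                         gene_b = character(), lls = numeric(),
                                         evidence = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  scored_network(tibble::tibble(
    gene_a = vapply(fields, `[`, "", 1),
    gene_b = vapply(fields, `[`, "", 2),
    lls = as.numeric(vapply(fields, `[`, "", 3)),
    evidence = vapply(fields, function(f) if (length(f) >= 4) f[4] else "", "")
  ))
}

#' Read a genes-by-columns numeric matrix from TSV
#'
#' First column holds gene ids, the header row names the samples, genomes or
#' conditions. Used for expression matrices, phylogenetic profile matrices
#' and knockout growth-score matrices alike.
#'
#' @param path Path to the TSV file.
#' @return A tibble whose first column is `gene`.
#' @export
read_matrix_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  names(tab)[1] <- "gene"
  tab$gene <- as.character(tab$gene)
  tab
}

#' @rdname read_matrix_tsv
#' @param mat A tibble whose first column is `gene`.
#' @export
write_matrix_tsv <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' @rdname read_gene_sets
#' @param annot A `cofnet_annotation` to write.
#' @export
write_gene_sets <- function(annot, path) {
  stopifnot(inherits(annot, "cofnet_annotation"))
  meta <- sprintf(
    "source=%s;evidence=%s;superpathway=%s",
    ifelse(is.na(annot$source), "NA", annot$source),
    vapply(annot$evidence, paste, "", collapse = ","),
    ifelse(annot$superpathway, "true", "false")
  )
  lines <- vapply(seq_len(nrow(annot)), function(i) {
    paste(c(annot$term[i], meta[i], annot$genes[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
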