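#' Cocitation significance (hypergeometric)
#'
#' Genes that operate in the same pathway tend to be mentioned in the same
#' articles. Given an article-to-gene index, the co-mention count of two
#' genes is tested against the hypergeometric null: with `N` articles, `m`
#' mentioning gene a, `n` mentioning gene b and `k` mentioning both, the
#' upper-tail probability `P(X >= k)` measures surprise; the raw link score
#' is `-log10 p` (higher is better).
#'
#' @param index A tibble (`article`, `gene`), one row per mention.
#' @param gene_a,gene_b Gene ids. Genes absent from the index yield `NA`
#'   (no score).
#' @param n_articles Total article count `N`; defaults to the number of
#'   distinct articles in `index` (pass the full corpus size when the index
#'   only lists gene-mentioning articles).
#' @return A list `(p, score, k, m, n, N)`.
#' @examples
#' idx <- tibble::tibble(article = c(1, 1, 2, 2), gene = c("a", "b", "a", "b"))
#' cocitation_pvalue(idx, "a", "b", n_articles = 10)$p  # 1/45
#' @export
cocitation_pvalue <- function(index, gene_a, gene_b, n_articles = NULL) {
  N <- n_articles %||% dplyr::n_distinct(index$article)
  arts_a <- unique(index$article[index$gene == gene_a])
  arts_b <- unique(index$article[index$gene == gene_b])
  if (!length(arts_a) || !length(arts_b)) {
    return(list(p = NA_real_, score = NA_real_, k = NA_integer_,
                m = length(arts_a), n = length(arts_b), N = N))
  }
  m <- length(arts_a); n <- length(arts_b)
  k <- length(intersect(arts_a, arts_b))
  p <- if (k == 0) 1 else stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  list(p = p, score = -log10(p), k = k, m = m, n = n, N = N)
}

#' @rdname cocitation_pvalue
#' @return `cocitation_linkset()` scores every co-mentioned pair (`k >= 1`)
#'   and returns a `cofnet_links` with evidence code `"CC"`.
#' @export
cocitation_linkset <- function(index, n_articles = NULL) {
  index <- dplyr::distinct(tibble::as_tibble(index)[c("article", "gene")])
  N <- n_articles %||% dplyr::n_distinct(index$article)
  counts <- dplyr::count(index, .data$gene, name = "m")
  pairs <- index |>
    dplyr::inner_join(index, by = "article", relationship = "many-to-many") |>
    dplyr::filter(.data$gene.x < .data$gene.y) |>
    dplyr::count(gene_a = .data$gene.x, gene_b = .data$gene.y, name = "k")
  pairs <- pairs |>
    dplyr::left_join(counts, by = c(gene_a = "gene")) |>
    dplyr::left_join(counts, by = c(gene_b = "gene"), suffix = c("_a", "_b"))
  p <- stats::phyper(pairs$k - 1, pairs$m_a, N - pairs$m_a, pairs$m_b,
                     lower.tail = FALSE)
  link_set(tibble::tibble(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                          score = -log10(pmax(p, .Machine$double.xmin))),
           "CC")
}

#' Coexpression (Pearson correlation) scoring
#'
#' The raw coexpression score of two genes is the Pearson correlation of
#' their expression profiles across the samples of one series; a series
#' must contribute more than 8 samples shared by both genes, and
#' zero-variance profiles are unscored.
#'
#' @param mat Expression tibble: first column `gene`, one column per sample.
#' @param gene_a,gene_b Gene ids.
#' @param min_samples Minimum shared (non-missing) samples, default 9.
#' @return Pearson r, or `NA` when unscorable.
#' @export
coexpression_pcc <- function(mat, gene_a, gene_b, min_samples = 9) {
  x <- unlist(mat[mat$gene == gene_a, -1])
  y <- unlist(mat[mat$gene == gene_b, -1])
  if (!length(x) || !length(y)) return(NA_real_)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_samples) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' @rdname coexpression_pcc
#' @param series_id Evidence label for the resulting link set (one
#'   coexpression series yields one link set, later integrated by
#'   [integrate_networks()]).
#' @return `coexpression_linkset()` returns a `cofnet_links` of all
#'   scorable gene pairs in the series.
#' @export
coexpression_linkset <- function(mat, series_id = "CX", min_samples = 9) {
  m <- as.matrix(mat[, -1])
  rownames(m) <- mat$gene
  if (ncol(m) < min_samples) {
    abort(sprintf("series has %d samples; need at least %d", ncol(m), min_samples))
  }
  keep <- apply(m, 1, function(r) sum(is.finite(r)) >= min_samples &&
                  stats::sd(r[is.finite(r)]) > 0)
  m <- m[keep, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  tab <- tibble::tibble(
    gene_a = rownames(cc)[idx[, 1]],
    gene_b = rownames(cc)[idx[, 2]],
    score = cc[idx]
  )
  link_set(tab[is.finite(tab$score), , drop = FALSE], series_id)
}

#' Domain co-occurrence: weighted mutual information score
#'
#' Proteins sharing domains often share function, and a rare shared domain
#' is far more informative than a ubiquitous one. Each domain `d` shared by
#' the two proteins contributes its rarity in bits, `-log2 f_d`, where
#' `f_d` is the fraction of the proteome carrying `d`; the score is the sum
#' over shared domains (0 when none are shared).
#'
#' @param domains A tibble (`protein`, `domain`), one row per assignment.
#' @param gene_a,gene_b Protein/gene ids (must be in the table).
#' @param proteome_size `P` used for domain frequencies; defaults to the
#'   number of distinct proteins in the table.
#' @return Non-negative score in bits.
#' @export
domain_wmi <- function(domains, gene_a, gene_b, proteome_size = NULL) {
  P <- proteome_size %||% dplyr::n_distinct(domains$protein)
  da <- unique(domains$domain[domains$protein == gene_a])
  db <- unique(domains$domain[domains$protein == gene_b])
  shared <- intersect(da, db)
  if (!length(shared)) return(0)
  f <- vapply(shared, function(d)
    dplyr::n_distinct(domains$protein[domains$domain == d]) / P, 0)
  sum(-log2(f))
}

#' @rdname domain_wmi
#' @return `domain_linkset()` scores every pair sharing >= 1 domain and
#'   returns a `cofnet_links` with evidence code `"DC"`.
#' @export
domain_linkset <- function(domains, proteome_size = NULL) {
  domains <- dplyr::distinct(tibble::as_tibble(domains)[c("protein", "domain")])
  P <- proteome_size %||% dplyr::n_distinct(domains$protein)
  freq <- dplyr::count(domains, .data$domain, name = "carriers")
  freq$w <- -log2(freq$carriers / P)
  scored <- domains |>
    dplyr::inner_join(domains, by = "domain", relationship = "many-to-many") |>
    dplyr::filter(.data$protein.x < .data$protein.y) |>
    dplyr::left_join(freq[c("domain", "w")], by = "domain") |>
    dplyr::group_by(gene_a = .data$protein.x, gene_b = .data$protein.y) |>
    dplyr::summarise(score = sum(.data$w), .groups = "drop")
  link_set(scored, "DC")
}

# Equal-frequency discretization into k bins via midranks; constant
# vectors collapse to a single bin.
discretize_profile <- function(x, k) {
  n <- length(x)
  pmax(1L, pmin(as.integer(ceiling(k * rank(x, ties.method = "average") / n)), k))
}

#' Phylogenetic-profile mutual information
#'
#' Two genes repeatedly co-inherited across genomes are likely
#' cofunctional. Each gene's profile of similarity scores across genomes is
#' discretized into `k` equal-frequency bins and the mutual information of
#' the joint histogram, `sum p(x,y) log2[p(x,y)/(p(x)p(y))]` (bits), is the
#' raw score. With taxon partitioning the Archaea-only and Bacteria-only
#' columns yield two separate link sets, to be merged downstream by the
#' weighted-sum integrator.
#'
#' @param profiles Profile tibble: first column `gene`, one column per
#'   genome, values >= 0 (e.g. normalized sequence-similarity scores).
#' @param gene_a,gene_b Gene ids.
#' @param k Number of equal-frequency bins (default 4).
#' @return Mutual information in bits (0 for a constant profile, with a
#'   warning).
#' @export
phyloprofile_mi <- function(profiles, gene_a, gene_b, k = 4) {
  x <- unlist(profiles[profiles$gene == gene_a, -1])
  y <- unlist(profiles[profiles$gene == gene_b, -1])
  stopifnot(length(x) == length(y), length(x) > 0)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("degenerate (constant) profile: MI = 0")
    return(0)
  }
  mi_bits(discretize_profile(x, k), discretize_profile(y, k))
}

mi_bits <- function(bx, by) {
  joint <- table(bx, by) / length(bx)
  px <- rowSums(joint); py <- colSums(joint)
  expected <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / expected[nz]))
}

#' @rdname phyloprofile_mi
#' @param genome_domains Optional named character vector mapping genome
#'   column names to `"Archaea"`/`"Bacteria"`; when given, one link set per
#'   taxonomic domain is returned (named list), otherwise a single set.
#' @param evidence_code Label for the link set(s); per-domain sets get a
#'   `PG_<domain>` label.
#' @return `phyloprofile_linkset()` returns a `cofnet_links` (or named list
#'   of them) over all gene pairs with nonzero MI.
#' @export
phyloprofile_linkset <- function(profiles, k = 4, genome_domains = NULL,
                                 evidence_code = "PG") {
  if (!is.null(genome_domains)) {
    doms <- unique(genome_domains)
    out <- lapply(doms, function(d) {
      cols <- names(genome_domains)[genome_domains == d]
      sub <- profiles[c("gene", intersect(cols, names(profiles)))]
      phyloprofile_linkset(sub, k = k,
                           evidence_code = paste0(evidence_code, "_", d))
    })
    return(setNames(out, doms))
  }
  m <- as.matrix(profiles[, -1])
  rownames(m) <- profiles$gene
  variable <- apply(m, 1, stats::sd) > 0
  m <- m[variable, , drop = FALSE]
  binned <- t(apply(m, 1, discretize_profile, k = k))
  genes <- rownames(m)
  n <- length(genes)
  if (n < 2) {
    return(link_set(tibble::tibble(gene_a = character(), gene_b = character(),
                                   score = numeric()), evidence_code))
  }
  idx <- utils::combn(n, 2)
  score <- vapply(seq_len(ncol(idx)), function(j)
    mi_bits(binned[idx[1, j], ], binned[idx[2, j], ]), 0)
  tab <- tibble::tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
                        score = score)
  link_set(tab[tab$score > 0, , drop = FALSE], evidence_code)
}

#' Gene-neighborhood scores from genome contexts
#'
#' Conserved chromosomal proximity of two genes' orthologs across many
#' genomes signals operon-like functional coupling. Two complementary
#' measures are provided. The distance-based score is minus the median
#' intergenic distance (bp) between the orthologs over genomes where both
#' occur, with occurrences on different replicons contributing a cap value;
#' higher (closer) is better. The probability-based score tests how often
#' the orthologs are within `window` gene slots of each other on one
#' replicon: with per-genome null probability `q = min(1, 2*window /
#' (n_slots - 1))` (averaged over the co-occurrence genomes), the score is
#' `-log10` of the binomial upper tail for the observed neighbor-genome
#' count.
#'
#' @param context Tibble (`genome`, `replicon`, `slot`, `start`, `end`,
#'   `gene`): one row per ortholog placement of a reference gene; `slot` is
#'   the gene's ordinal position on its replicon.
#' @param gene_a,gene_b Reference gene ids.
#' @param min_genomes Minimum co-occurrence genomes (default 3); fewer
#'   yields `NA` (no score).
#' @param cap Distance (bp) charged for different-replicon co-occurrence.
#' @return `gn_distance_score()`: minus the median distance, or `NA`.
#' @export
gn_distance_score <- function(context, gene_a, gene_b, min_genomes = 3,
                              cap = 1e6) {
  both <- gn_cooccurrence(context, gene_a, gene_b)
  if (nrow(both) < min_genomes) return(NA_real_)
  d <- ifelse(both$replicon_a == both$replicon_b,
              pmax(0, pmax(both$start_a, both$start_b) -
                     pmin(both$end_a, both$end_b)),
              cap)
  -stats::median(d)
}

#' @rdname gn_distance_score
#' @param window Neighborhood width in gene slots (default 1: adjacency).
#' @return `gn_probability_score()`: `-log10 P(X >= x)`, or `NA`.
#' @export
gn_probability_score <- function(context, gene_a, gene_b, window = 1,
                                 min_genomes = 3) {
  both <- gn_cooccurrence(context, gene_a, gene_b)
  G <- nrow(both)
  if (G < min_genomes) return(NA_real_)
  slots <- context |>
    dplyr::distinct(.data$genome, .data$replicon, .data$slot) |>
    dplyr::count(.data$genome, name = "n_slots")
  both <- dplyr::left_join(both, slots, by = "genome")
  neighbor <- both$replicon_a == both$replicon_b &
    abs(both$slot_a - both$slot_b) <= window
  q <- mean(pmin(1, 2 * window / pmax(1, both$n_slots - 1)))
  x <- sum(neighbor)
  if (x == 0) return(0)
  p <- stats::pbinom(x - 1, G, q, lower.tail = FALSE)
  -log10(max(p, .Machine$double.xmin))
}

gn_cooccurrence <- function(context, gene_a, gene_b) {
  ca <- context[context$gene == gene_a, , drop = FALSE]
  cb <- context[context$gene == gene_b, , drop = FALSE]
  dplyr::inner_join(
    tibble::as_tibble(ca), tibble::as_tibble(cb),
    by = "genome", suffix = c("_a", "_b"), relationship = "many-to-many"
  )
}

#' @rdname gn_distance_score
#' @param genes Genes to score (default: all reference genes in `context`);
#'   all pairs co-occurring in `min_genomes`+ genomes are scored.
#' @param method `"distance"` or `"probability"`.
#' @return `gn_linkset()` returns a `cofnet_links` (evidence code
#'   `GN_dist`/`GN_prob`).
#' @export
gn_linkset <- function(context, method = c("distance", "probability"),
                       genes = NULL, window = 1, min_genomes = 3, cap = 1e6) {
  method <- match.arg(method)
  genes <- sort(genes %||% unique(context$gene))
  if (length(genes) < 2) abort("need at least 2 genes")
  idx <- utils::combn(length(genes), 2)
  score <- vapply(seq_len(ncol(idx)), function(j) {
    a <- genes[idx[1, j]]; b <- genes[idx[2, j]]
    if (method == "distance") {
      gn_distance_score(context, a, b, min_genomes = min_genomes, cap = cap)
    } else {
      gn_probability_score(context, a, b, window = window,
                           min_genomes = min_genomes)
    }
  }, 0)
  tab <- tibble::tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]],
                        score = score)
  link_set(tab[is.finite(tab$score), , drop = FALSE],
           if (method == "distance") "GN_dist" else "GN_prob")
}

#' Protein-protein interaction edges as benchmarked evidence
#'
#' Binary interaction sets (high-throughput screens, HT; literature-curated
#' small/medium-scale interactions, LC) carry no intrinsic score: every
#' link is given raw score 1, producing single-bin evidence whose LLS is
#' learned wholesale from its gold-standard overlap. Per-source sets are
#' kept separate so each source is benchmarked on its own before
#' weighted-sum merging.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` (self-pairs are
#'   dropped with a logged count).
#' @param label Evidence code, `"HT"` or `"LC"` (a source suffix such as
#'   `"HT_y2h"` is allowed).
#' @return A `cofnet_links` with all scores 1.
#' @export
ppi_to_linkset <- function(edges, label) {
  edges <- tibble::as_tibble(edges)
  edges$score <- 1
  link_set(edges, label)
}
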