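#' Permutation test for network targeting
#'
#' Tests whether the number of network genes that are both bound and
#' down-regulated exceeds chance: the statistic is
#' `|network ∩ bound ∩ down|`, the null redraws gene sets of the network's
#' size uniformly without replacement from the universe, and
#' `perm_p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param network Character vector of network gene ids.
#' @param bound_genes Character vector of genes with proximal binding.
#' @param down_genes Character vector of down-regulated genes.
#' @param universe Character vector of all eligible genes (e.g. all
#'   expressed genes).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed for reproducibility.
#' @return One-row tibble of class `enrichment_result`: `observed`,
#'   `expected` (null mean), `fold`, `perm_p`, `n_perm`, `n_network`,
#'   `n_universe`.
#' @export
network_targeting_test <- function(network, bound_genes, down_genes,
                                   universe, n_perm = 10000L, seed = NULL) {
  universe <- unique(universe)
  dropped <- setdiff(network, universe)
  if (length(dropped) > 0L) {
    warn(paste0(length(dropped), " network gene(s) absent from universe,",
                " dropped: ", paste(head(dropped, 10), collapse = ", ")))
  }
  network <- intersect(unique(network), universe)
  if (length(network) == 0L) abort("no network gene left in universe")
  if (length(network) > length(universe)) {
    abort("network larger than universe")
  }
  target <- intersect(intersect(bound_genes, down_genes), universe)
  observed <- length(intersect(network, target))
  is_target <- universe %in% target
  m <- length(network)
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      sum(is_target[sample.int(length(universe), m)])
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  enrichment_row(observed, null, n_perm,
                 n_network = m, n_universe = length(universe))
}

#' Permutation enrichment of a binary label among candidate genes
#'
#' Observed statistic: labeled genes among the candidates; expected:
#' candidate count times the label rate in the universe; null: candidate
#' sets redrawn uniformly from the universe.
#'
#' @param candidates Character vector of candidate gene ids (subset of the
#'   universe).
#' @param labeled_universe Tibble with `gene_id` and logical `label`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return One-row tibble of class `enrichment_result` (see
#'   [network_targeting_test()]); `expected` here is the closed-form
#'   `|candidates| * label rate`.
#' @export
labeled_set_enrichment <- function(candidates, labeled_universe,
                                   n_perm = 10000L, seed = NULL) {
  stopifnot(all(c("gene_id", "label") %in% names(labeled_universe)))
  universe <- labeled_universe$gene_id
  label <- as.logical(labeled_universe$label)
  stopifnot(all(candidates %in% universe))
  m <- length(candidates)
  observed <- sum(label[match(candidates, universe)])
  rate <- mean(label)
  if (rate == 0) {
    out <- enrichment_row(observed, rep(0, 1), n_perm,
                          n_network = m, n_universe = length(universe))
    out$expected <- 0
    out$fold <- NA_real_
    out$perm_p <- 1
    return(out)
  }
  run <- function() {
    vapply(seq_len(n_perm), function(i) {
      sum(label[sample.int(length(universe), m)])
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- enrichment_row(observed, null, n_perm,
                        n_network = m, n_universe = length(universe))
  out$expected <- m * rate
  out$fold <- observed / out$expected
  out
}

enrichment_row <- function(observed, null, n_perm, n_network, n_universe) {
  out <- tibble(
    observed = observed,
    expected = mean(null),
    fold = if (mean(null) > 0) observed / mean(null) else
      if (observed == 0) NA_real_ else Inf,
    perm_p = (1 + sum(null >= observed)) / (length(null) + 1),
    n_perm = n_perm,
    n_network = n_network,
    n_universe = n_universe
  )
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Annotate network genes with binding and regulation status
#'
#' For each network gene: `bound_at_tss` when a peak lies within
#' `max_dist` bp of the TSS, `bound_in_gene` when a peak lies within
#' `max_dist` bp of the gene body (bp gap; overlap counts as 0), and the
#' differential-expression class from [classify_de()] output. Genes absent
#' from the gene models are flagged `missing`.
#'
#' @param network Character vector of network gene ids.
#' @param bound_regions Peak tibble.
#' @param de_results Tibble with `feature_id` and `class` (gene-level DE
#'   calls), or NULL.
#' @param genes Gene tibble.
#' @param max_dist Proximity in bp (default 500, inclusive).
#' @return Tibble with one row per network gene: `gene_id`, `missing`,
#'   `bound_at_tss`, `bound_in_gene`, `de_class`.
#' @export
annotate_network <- function(network, bound_regions, de_results, genes,
                             max_dist = 500L) {
  validate_genes(genes)
  pk <- peaks_to_gr(as_peaks(bound_regions))
  idx <- match(network, genes$gene_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warn(paste0("network gene(s) absent from gene models: ",
                paste(head(network[missing], 10), collapse = ", ")))
  }
  bound_at_tss <- rep(NA, length(network))
  bound_in_gene <- rep(NA, length(network))
  present <- which(!missing)
  if (length(present) > 0L) {
    g <- genes[idx[present], ]
    tss_gr <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$tss + 1L, width = 1L))
    body_gr <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$body_start + 1L, g$body_end))
    near_tss <- GenomicRanges::distanceToNearest(tss_gr, pk)
    near_body <- GenomicRanges::distanceToNearest(body_gr, pk)
    d_tss <- rep(Inf, length(present))
    d_tss[S4Vectors::queryHits(near_tss)] <-
      S4Vectors::mcols(near_tss)$distance
    d_body <- rep(Inf, length(present))
    d_body[S4Vectors::queryHits(near_body)] <-
      S4Vectors::mcols(near_body)$distance
    bound_at_tss[present] <- d_tss <= max_dist
    bound_in_gene[present] <- d_body <= max_dist
  }
  de_class <- rep(NA_character_, length(network))
  if (!is.null(de_results)) {
    de_class <- de_results$class[match(network, de_results$feature_id)]
  }
  tibble(gene_id = network, missing = missing,
         bound_at_tss = bound_at_tss, bound_in_gene = bound_in_gene,
         de_class = de_class)
}

#' Load the curated adipogenic network gene set shipped with the package
#'
#' A curated list of adipogenic gene-regulatory-network members (core
#' transcription factors and signaling genes of fat-cell differentiation),
#' assembled from the WikiPathways adipogenesis scaffold and standard
#' reviews. Useful for examples and as the default network in targeting
#' tests; ids are mouse gene symbols.
#'
#' @return Character vector of gene symbols.
#' @export
adipogenic_network_genes <- function() {
  read_gene_set(system.file("extdata", "adipogenic_network_genes.txt",
                            package = "adipodyn", mustWork = TRUE))
}
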