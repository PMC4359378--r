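# Internal: peak tibble (0-based half-open) -> GRanges (1-based closed).
peaks_to_gr <- function(peaks, layout = NULL) {
  seqlen <- NULL
  if (!is.null(layout)) {
    unknown <- setdiff(unique(peaks$chrom), layout$chrom)
    if (length(unknown) > 0L) {
      abort(paste0("chromosome(s) absent from genome layout: ",
                   paste(unknown, collapse = ", ")))
    }
    seqlen <- setNames(layout$length, layout$chrom)
  }
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end),
                         seqlengths = seqlen)
}

#' Merge peak calls from two callers into common bound regions
#'
#' Takes the union of two peak sets, coalescing overlapping or bookended
#' (0-gap) intervals. The summit of a merged region is the summit of the
#' highest-scoring constituent interval; when no constituent carries a
#' score, the merged midpoint is used.
#'
#' @param set_a,set_b Peak tibbles.
#' @param layout Optional genome layout tibble (`chrom`, `length`) used to
#'   reject intervals on unknown chromosomes.
#' @return A sorted, internally non-overlapping peak tibble; `source` records
#'   the contributing callers.
#' @export
merge_peak_calls <- function(set_a, set_b, layout = NULL) {
  a <- as_peaks(set_a)
  b <- as_peaks(set_b)
  all_pk <- bind_rows(a, b)
  gr <- peaks_to_gr(all_pk, layout)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  start <- GenomicRanges::start(red) - 1L
  end <- GenomicRanges::end(red)
  summit <- map_int(seq_along(red), function(i) {
    members <- all_pk[revmap[[i]], ]
    scored <- !is.na(members$score) & !is.na(members$summit)
    if (any(scored)) {
      members$summit[scored][which.max(members$score[scored])]
    } else if (any(!is.na(members$summit))) {
      members$summit[!is.na(members$summit)][1]
    } else {
      as.integer((start[i] + end[i]) %/% 2L)
    }
  })
  source <- map_chr(seq_along(red), function(i) {
    src <- unique(all_pk$source[revmap[[i]]])
    paste(src[!is.na(src)], collapse = "+")
  })
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = start, end = end,
    name = sprintf("merged_%05d", seq_along(red)),
    score = map_dbl(as.list(revmap), ~ suppressWarnings(
      max(all_pk$score[.x], na.rm = TRUE))),
    strand = NA_character_,
    summit = summit,
    source = ifelse(nzchar(source), source, NA_character_)
  )
  out$score[!is.finite(out$score)] <- NA_real_
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Annotate peaks by genomic category with the priority scheme
#'
#' Each peak is assigned, in this order, to: `TSS` (within +-`tss_window` bp
#' of an annotated TSS), `exon` (overlaps an exon but no TSS window),
#' `intron` (overlaps a gene body but neither TSS window nor exon),
#' `proximal` (within `proximal_dist` bp of a gene body but none of the
#' above) or `distal`. Overlap means at least 1 bp of intersection; the TSS
#' window covers positions `tss - w` to `tss + w` inclusive.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble.
#' @param tss_window Half-width of the TSS window in bp (default 500).
#' @param proximal_dist Maximum gene distance for `proximal` (default 10000).
#' @return `peaks` with an added `annotation` factor column; the categories
#'   partition the peak set.
#' @export
annotate_peaks <- function(peaks, genes, tss_window = 500L,
                           proximal_dist = 10000L) {
  peaks <- as_peaks(peaks)
  validate_genes(genes)
  pk <- peaks_to_gr(peaks)
  tss_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$tss - tss_window, 0L) + 1L,
                     genes$tss + tss_window + 1L))
  exon_gr <- GenomicRanges::GRanges(
    rep(genes$chrom, lengths(genes$exon_starts)),
    IRanges::IRanges(unlist(genes$exon_starts) + 1L,
                     unlist(genes$exon_ends)))
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$body_start + 1L, genes$body_end))
  in_tss <- GenomicRanges::countOverlaps(pk, tss_gr) > 0
  in_exon <- GenomicRanges::countOverlaps(pk, exon_gr) > 0
  in_body <- GenomicRanges::countOverlaps(pk, body_gr) > 0
  near <- GenomicRanges::distanceToNearest(pk, body_gr)
  dist <- rep(Inf, length(pk))
  dist[S4Vectors::queryHits(near)] <- S4Vectors::mcols(near)$distance
  ann <- rep("distal", length(pk))
  ann[dist <= proximal_dist] <- "proximal"
  ann[in_body] <- "intron"
  ann[in_exon] <- "exon"
  ann[in_tss] <- "TSS"
  peaks$annotation <- factor(ann,
    levels = c("TSS", "exon", "intron", "proximal", "distal"))
  peaks
}

#' Assign peaks to all proximal genes
#'
#' A peak is assigned to every gene whose body lies within `max_dist` bp
#' (bookended intervals have distance 0; overlap gives distance 0). The
#' mapping is returned in long form and can be nested in either direction.
#'
#' @param peaks Peak tibble.
#' @param genes Gene tibble.
#' @param max_dist Maximum distance in bp, inclusive (default 10000).
#' @return Tibble with `peak_id`, `gene_id`, `distance`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_dist = 10000L) {
  peaks <- as_peaks(peaks)
  validate_genes(genes)
  pk <- peaks_to_gr(peaks)
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$body_start + 1L, genes$body_end))
  # distance <= max_dist <=> closed-interval gap; widen gene bodies and
  # intersect, then compute exact distances on the hit pairs
  hits <- GenomicRanges::findOverlaps(pk, body_gr, maxgap = max_dist)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(pk[qi], body_gr[si])
  keep <- d <= max_dist
  tibble(peak_id = interval_ids(peaks)[qi[keep]],
         gene_id = genes$gene_id[si[keep]],
         distance = as.integer(d[keep])) |>
    arrange(.data$peak_id, .data$gene_id)
}

#' Closest gene to each peak summit
#'
#' The closest gene minimizes the distance from the peak summit to the gene
#' TSS (same chromosome). Ties resolve to the lexicographically smallest
#' `gene_id`. The signed distance is negative when the summit lies upstream
#' of the TSS with respect to the gene's strand.
#'
#' @param peaks Peak tibble; peaks without a summit use the interval
#'   midpoint.
#' @param genes Gene tibble.
#' @return `peaks` with added `closest_gene` and `distance_to_tss` columns
#'   (`NA` when the chromosome carries no gene).
#' @export
closest_gene <- function(peaks, genes) {
  peaks <- as_peaks(peaks)
  validate_genes(genes)
  summit <- ifelse(is.na(peaks$summit),
                   (peaks$start + peaks$end) %/% 2L, peaks$summit)
  closest <- rep(NA_character_, nrow(peaks))
  signed <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    g <- genes[genes$chrom == chr, ]
    if (nrow(g) == 0L) next
    pi <- which(peaks$chrom == chr)
    for (i in pi) {
      d <- abs(summit[i] - g$tss)
      cand <- which(d == min(d))
      j <- cand[order(g$gene_id[cand])][1]
      closest[i] <- g$gene_id[j]
      raw <- summit[i] - g$tss[j]
      signed[i] <- if (g$strand[j] == "+") raw else -raw
    }
  }
  peaks$closest_gene <- closest
  peaks$distance_to_tss <- signed
  peaks
}

#' Randomly re-place peaks on their own chromosomes
#'
#' Each interval is moved to a uniformly random start position on its own
#' chromosome with its length (and summit offset) preserved; placements that
#' would leave the chromosome are impossible by construction. Used to build
#' shifted-peak background sets for enrichment tests.
#'
#' @param peaks Peak tibble.
#' @param layout Genome layout tibble (`chrom`, `length`).
#' @param seed Optional integer seed for a deterministic shift.
#' @return Peak tibble with identical per-chromosome counts and lengths.
#' @export
shift_peaks <- function(peaks, layout, seed = NULL) {
  peaks <- as_peaks(peaks)
  len <- setNames(layout$length, layout$chrom)
  unknown <- setdiff(unique(peaks$chrom), names(len))
  if (length(unknown) > 0L) {
    abort(paste0("chromosome(s) absent from layout: ",
                 paste(unknown, collapse = ", ")))
  }
  widths <- peaks$end - peaks$start
  room <- len[peaks$chrom] - widths
  if (any(room < 0)) abort("interval longer than its chromosome")
  draw <- function() {
    new_start <- as.integer(floor(runif(nrow(peaks)) * (room + 1)))
    out <- peaks
    out$summit <- ifelse(is.na(peaks$summit), NA_integer_,
                         as.integer(new_start + (peaks$summit - peaks$start)))
    out$start <- new_start
    out$end <- as.integer(new_start + widths)
    arrange(out, .data$chrom, .data$start, .data$end)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Count overlapping peaks between two sets
#'
#' @param set_a,set_b Peak tibbles.
#' @return List with `n` (number of `set_a` intervals intersecting at least
#'   1 bp of `set_b`) and `pairs`, a tibble of overlapping index pairs.
#' @export
overlap_peaks <- function(set_a, set_b) {
  a <- as_peaks(set_a)
  b <- as_peaks(set_b)
  ga <- peaks_to_gr(a)
  gb <- peaks_to_gr(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qi <- S4Vectors::queryHits(hits)
  list(
    n = length(unique(qi)),
    pairs = tibble(a_index = qi, b_index = S4Vectors::subjectHits(hits))
  )
}

#' Co-binding enrichment against a shifted-peak null
#'
#' Compares the observed number of `set_a` peaks overlapping `set_b` with
#' the mean overlap of `n_shifts` randomly shifted copies of `set_a`.
#' Reports the fold enrichment, a two-sided Fisher's exact p on the 2x2
#' table (observed vs expected overlapping / non-overlapping counts) and an
#' always-valid permutation p-value
#' `(1 + #{shifts >= observed}) / (n_shifts + 1)`.
#'
#' @param set_a,set_b Peak tibbles.
#' @param layout Genome layout tibble.
#' @param n_shifts Number of shifted null sets (default 100).
#' @param seed Optional seed for reproducible shifts.
#' @return One-row tibble: `observed`, `expected`, `fold`, `fisher_p`,
#'   `perm_p`, `n_shifts`, `n_a`.
#' @export
overlap_enrichment <- function(set_a, set_b, layout, n_shifts = 100L,
                               seed = NULL) {
  stopifnot(n_shifts >= 1L)
  a <- as_peaks(set_a)
  obs <- overlap_peaks(a, set_b)$n
  run <- function() {
    vapply(seq_len(n_shifts), function(i) {
      overlap_peaks(shift_peaks(a, layout), set_b)$n
    }, numeric(1))
  }
  null_counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  expected <- mean(null_counts)
  n_a <- nrow(a)
  if (expected == 0 && obs > 0) {
    fold <- Inf
    fisher_p <- NA_real_
  } else {
    fold <- obs / expected
    tab <- matrix(c(obs, n_a - obs,
                    round(expected), n_a - round(expected)),
                  nrow = 2, byrow = TRUE)
    fisher_p <- fisher.test(tab)$p.value
  }
  tibble(observed = obs, expected = expected, fold = fold,
         fisher_p = fisher_p,
         perm_p = (1 + sum(null_counts >= obs)) / (n_shifts + 1),
         n_shifts = n_shifts, n_a = n_a)
}

#' Hypergeometric category enrichment against shifted peaks
#'
#' The universe is the real peaks pooled with `n_shifts` shifted copies;
#' for each feature set the upper hypergeometric tail of the observed
#' number of overlapping real peaks is computed.
#'
#' @param peaks Peak tibble.
#' @param feature_sets Named list of peak tibbles (e.g. promoters, CpG-like
#'   features, exons).
#' @param layout Genome layout tibble.
#' @param n_shifts Number of shifted copies forming the background
#'   (default 10).
#' @param seed Optional seed.
#' @return Tibble with one row per feature set: `observed`, `expected`,
#'   `fold`, `p` (upper hypergeometric tail). Empty feature sets yield
#'   `p = 1` and missing fold.
#' @export
category_enrichment <- function(peaks, feature_sets, layout, n_shifts = 10L,
                                seed = NULL) {
  peaks <- as_peaks(peaks)
  build <- function() {
    map(seq_len(n_shifts), function(i) shift_peaks(peaks, layout))
  }
  shifted <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  background <- bind_rows(shifted)
  n_real <- nrow(peaks)
  n_univ <- n_real + nrow(background)
  imap(feature_sets, function(fs, nm) {
    if (is.null(fs) || nrow(fs) == 0L) {
      return(tibble(feature = nm, observed = 0L, expected = NA_real_,
                    fold = NA_real_, p = 1))
    }
    obs <- overlap_peaks(peaks, fs)$n
    bg <- overlap_peaks(background, fs)$n
    m <- obs + bg
    expected <- n_real * m / n_univ
    tibble(feature = nm, observed = obs, expected = expected,
           fold = if (expected > 0) obs / expected else NA_real_,
           p = phyper(obs - 1, m, n_univ - m, n_real, lower.tail = FALSE))
  }) |> bind_rows()
}

#' Summit-centered normalized signal matrix
#'
#' Tags are extended to `extend` bp in their strand direction; per-base
#' coverage is summed in `window/bin` bins of `bin` bp centered on each
#' summit, divided by the sample's size factor, and log2(x+1)-transformed.
#' Rows (summits) are ordered by decreasing row mean of the reference
#' sample. Summits closer than `window/2` to a chromosome edge are
#' zero-padded and flagged.
#'
#' @param tags Tibble with `sample_id`, `chrom`, `pos`, `strand`
#'   (`"+"`/`"-"`; anything else treated as `"+"`).
#' @param summits Peak tibble (summits taken from the `summit` column, or
#'   interval midpoints when absent).
#' @param layout Genome layout tibble.
#' @param window Total window in bp (default 2000).
#' @param bin Bin width in bp (default 5).
#' @param extend Tag extension in bp (default 200).
#' @param size_factors Named per-sample size factors (default all 1).
#' @param reference_sample Sample id used for row ordering (default first).
#' @return List of class `signal_matrix`: `matrices` (one
#'   summits x bins matrix per sample, rows ordered), `order` (summit
#'   permutation), `flagged` (edge-clipped summit indicator).
#' @export
summit_signal_matrix <- function(tags, summits, layout, window = 2000L,
                                 bin = 5L, extend = 200L,
                                 size_factors = NULL,
                                 reference_sample = NULL) {
  stopifnot(window %% bin == 0L)
  summits <- as_peaks(summits)
  pos <- ifelse(is.na(summits$summit),
                (summits$start + summits$end) %/% 2L, summits$summit)
  half <- window %/% 2L
  n_bins <- window %/% bin
  chrom_len <- setNames(layout$length, layout$chrom)
  sample_ids <- unique(tags$sample_id)
  if (is.null(size_factors)) {
    size_factors <- setNames(rep(1, length(sample_ids)), sample_ids)
  }
  stopifnot(all(size_factors > 0))
  if (is.null(reference_sample)) reference_sample <- sample_ids[1]

  flagged <- pos - half < 0 | pos + half > chrom_len[summits$chrom]
  mats <- map(sample_ids, function(s) {
    tg <- tags[tags$sample_id == s, , drop = FALSE]
    minus <- !is.na(tg$strand) & tg$strand == "-"
    frag_start <- ifelse(minus, tg$pos - extend + 1L, tg$pos)
    frag_end <- frag_start + extend  # half-open
    m <- matrix(0, nrow = nrow(summits), ncol = n_bins)
    for (chr in unique(summits$chrom)) {
      sel <- tg$chrom == chr
      ridx <- which(summits$chrom == chr)
      if (!any(sel)) next
      cov <- IRanges::coverage(
        IRanges::IRanges(pmax(frag_start[sel], 0L) + 1L,
                         pmin(frag_end[sel], chrom_len[chr])),
        width = chrom_len[chr])
      for (i in ridx) {
        lo <- pos[i] - half
        hi <- pos[i] + half
        clip_lo <- max(lo, 0L)
        clip_hi <- min(hi, chrom_len[chr])
        if (clip_lo >= clip_hi) next
        v <- as.numeric(S4Vectors::window(cov, clip_lo + 1L, clip_hi))
        full <- numeric(window)
        full[(clip_lo - lo + 1L):(clip_lo - lo + length(v))] <- v
        m[i, ] <- colSums(matrix(full, nrow = bin))
      }
    }
    log2(m / size_factors[[s]] + 1)
  })
  names(mats) <- sample_ids
  ord <- order(rowMeans(mats[[reference_sample]]), decreasing = TRUE)
  mats <- map(mats, function(m) m[ord, , drop = FALSE])
  structure(list(matrices = mats, order = ord, flagged = flagged[ord],
                 bin = bin, window = window),
            class = "signal_matrix")
}
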