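#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the toy-genome, peak-time-course, count-matrix,
#' sequence and screen generators, with validation. Defaults describe the
#' study conditions the analysis modules are tested under: a two-chromosome
#' megabase-scale genome, a four-timepoint binding time course with planted
#' static/early-only/late-only regions and co-binding with a second factor,
#' NB counts at moderate overdispersion, and a 734-construct screen with a
#' 47.9% mean control differentiation level.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes Number of genes to place.
#' @param n_peaks Number of bound regions in the time course.
#' @param peak_len_mean Mean peak length in bp.
#' @param frac_cobound Fraction of peaks planted as co-bound (summits within
#'   100 bp of a second-factor peak).
#' @param frac_early_only,frac_late_only Fractions of peaks planted as
#'   early-only / late-only (their sum must be at most 1).
#' @param planted_log2fc Log2 fold change planted between the bound and
#'   depleted phases of dynamic regions (and used for planted DE effects).
#' @param nb_dispersion NB dispersion (variance = mean + dispersion *
#'   mean^2); 0 gives Poisson counts.
#' @param depth_mean Expected tag count per peak in its bound phase.
#' @param seq_gc GC content of the background sequence.
#' @param motif_plant_rate Per-peak probability of an exact consensus motif
#'   insertion near the summit.
#' @param screen List of screen settings, see [screen_config()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_len = 1e6, n_genes = 150L,
                       n_peaks = 1000L, peak_len_mean = 300L,
                       frac_cobound = 0.3, frac_early_only = 0.1,
                       frac_late_only = 0.15, planted_log2fc = 2,
                       nb_dispersion = 0.1, depth_mean = 50,
                       seq_gc = 0.45, motif_plant_rate = 0.4,
                       screen = screen_config()) {
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
              n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
              peak_len_mean = as.integer(peak_len_mean),
              frac_cobound = frac_cobound,
              frac_early_only = frac_early_only,
              frac_late_only = frac_late_only,
              planted_log2fc = planted_log2fc,
              nb_dispersion = nb_dispersion, depth_mean = depth_mean,
              seq_gc = seq_gc, motif_plant_rate = motif_plant_rate,
              screen = screen)
  with(cfg, {
    stopifnot(n_chrom > 0, chrom_len > 0, n_genes > 0, n_peaks > 0,
              peak_len_mean > 0, nb_dispersion >= 0, depth_mean > 0)
    fr <- c(frac_cobound, frac_early_only, frac_late_only,
            seq_gc, motif_plant_rate)
    stopifnot(all(fr >= 0), all(fr <= 1),
              frac_early_only + frac_late_only <= 1)
  })
  structure(cfg, class = "sim_config")
}

#' Screen-generator settings
#'
#' @param n_constructs Number of (non-control) constructs.
#' @param n_neg_controls Negative-control wells per replicate.
#' @param n_replicates Replicates (plates) per construct.
#' @param control_pdc_mean Mean control differentiation fraction
#'   (default 0.479).
#' @param control_pdc_sd Control standard deviation (default 0.05).
#' @param planted_effect_sd_units Planted-hit shift in control-sd units.
#' @param planted_fc Planted-hit target fold change over the control mean.
#' @param n_planted Number of planted enhancer constructs.
#' @return A named list.
#' @export
screen_config <- function(n_constructs = 734L, n_neg_controls = 30L,
                          n_replicates = 3L, control_pdc_mean = 0.479,
                          control_pdc_sd = 0.05,
                          planted_effect_sd_units = 10, planted_fc = 2,
                          n_planted = 10L) {
  stopifnot(n_constructs > 0, n_neg_controls >= 2, n_replicates >= 1,
            control_pdc_mean > 0, control_pdc_mean < 1, control_pdc_sd > 0,
            n_planted >= 0, n_planted <= n_constructs)
  list(n_constructs = as.integer(n_constructs),
       n_neg_controls = as.integer(n_neg_controls),
       n_replicates = as.integer(n_replicates),
       control_pdc_mean = control_pdc_mean,
       control_pdc_sd = control_pdc_sd,
       planted_effect_sd_units = planted_effect_sd_units,
       planted_fc = planted_fc, n_planted = as.integer(n_planted))
}

# Place non-overlapping intervals of given widths on one chromosome by a
# broken-stick gap partition; deterministic under the caller's RNG state.
place_intervals <- function(widths, chrom_len) {
  k <- length(widths)
  if (k == 0L) return(integer(0))
  slack <- chrom_len - sum(widths)
  if (slack < 0) {
    abort("intervals cannot be placed without overlap: combined length exceeds the chromosome")
  }
  gaps <- diff(sort(c(0, runif(k), 1))) * slack
  starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, widths[-k]))
  as.integer(floor(starts))
}

#' Generate a toy genome: layout, gene models, sequences
#'
#' Genes get non-overlapping bodies (1 to 5 exons each, TSS at the
#' strand-appropriate edge); background sequence is i.i.d. at the requested
#' GC content. Fully deterministic under `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param with_sequences Generate chromosome sequences too (default TRUE).
#' @return List with `layout` (tibble `chrom`, `length`), `genes` (gene
#'   tibble) and `seqs` (named character vector, or NULL).
#' @export
sim_genome <- function(config = sim_config(), seed = 1L,
                       with_sequences = TRUE) {
  withr::with_seed(seed, {
    chroms <- sprintf("chr%d", seq_len(config$n_chrom))
    layout <- tibble(chrom = chroms, length = config$chrom_len)
    n_per <- table(factor(sample(chroms, config$n_genes, replace = TRUE),
                          levels = chroms))
    genes <- map_dfr(chroms, function(chr) {
      k <- n_per[[chr]]
      if (k == 0L) return(NULL)
      widths <- as.integer(round(runif(k, 2000, 8000)))
      starts <- place_intervals(widths, config$chrom_len)
      strand <- sample(c("+", "-"), k, replace = TRUE)
      exons <- map2(starts, widths, function(s, w) {
        n_ex <- sample.int(5L, 1L)
        brk <- sort(sample(seq(s, s + w), 2L * n_ex))
        list(starts = brk[seq(1, 2 * n_ex, 2)],
             ends = brk[seq(2, 2 * n_ex, 2)])
      })
      tibble(
        gene_id = NA_character_, chrom = chr, strand = strand,
        tss = ifelse(strand == "+", starts,
                     as.integer(starts + widths - 1L)),
        body_start = starts, body_end = as.integer(starts + widths),
        exon_starts = map(exons, ~ as.integer(.x$starts)),
        exon_ends = map(exons, ~ as.integer(.x$ends))
      )
    })
    genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
    # drop zero-width exons that ties in the break sample can produce
    keep <- map2(genes$exon_starts, genes$exon_ends, function(s, e) s < e)
    genes$exon_starts <- map2(genes$exon_starts, keep, ~ .x[.y])
    genes$exon_ends <- map2(genes$exon_ends, keep, ~ .x[.y])
    empty <- lengths(genes$exon_starts) == 0L
    genes$exon_starts[empty] <- map(which(empty),
                                    ~ genes$body_start[.x])
    genes$exon_ends[empty] <- map(which(empty), ~ genes$body_end[.x])
    validate_genes(genes)
    seqs <- NULL
    if (with_sequences) {
      gc <- config$seq_gc
      prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
      seqs <- setNames(vapply(chroms, function(chr) {
        paste(sample(c("A", "C", "G", "T"), config$chrom_len,
                     replace = TRUE, prob = prob), collapse = "")
      }, ""), chroms)
    }
    list(layout = layout, genes = genes, seqs = seqs)
  })
}

#' Generate a multi-timepoint peak set with planted dynamics and co-binding
#'
#' Plants exact numbers of early-only (bound at timepoints 1-2 only),
#' late-only (timepoints 3-4 only) and static regions; per-timepoint
#' expected tag counts encode a `2^planted_log2fc` change between the bound
#' and depleted phases. A configured fraction of peaks is co-bound: a
#' second-factor peak is placed with its summit within 100 bp.
#'
#' @param config A [sim_config()].
#' @param genome Output of [sim_genome()].
#' @param seed Integer seed.
#' @return List with `truth` (peak tibble plus `class`, `cobound`,
#'   `mu_t1..mu_t4`), `peak_sets` (named list of per-timepoint peak
#'   tibbles), and `second_factor` (peak tibble).
#' @export
sim_peak_timecourse <- function(config = sim_config(), genome, seed = 1L) {
  withr::with_seed(seed, {
    layout <- genome$layout
    n <- config$n_peaks
    chroms <- sample(layout$chrom, n, replace = TRUE,
                     prob = layout$length)
    widths <- pmax(50L, as.integer(round(
      rnorm(n, config$peak_len_mean, 0.2 * config$peak_len_mean))))
    peaks <- map_dfr(layout$chrom, function(chr) {
      sel <- chroms == chr
      if (!any(sel)) return(NULL)
      w <- widths[sel]
      s <- place_intervals(w, layout$length[layout$chrom == chr])
      tibble(chrom = chr, start = s, end = as.integer(s + w))
    })
    n <- nrow(peaks)
    peaks$name <- sprintf("peak_%05d", seq_len(n))
    peaks$score <- round(runif(n, 1, 100), 2)
    peaks$strand <- NA_character_
    off <- as.integer(floor((peaks$end - peaks$start) *
                              runif(n, 0.3, 0.7)))
    peaks$summit <- peaks$start + off
    peaks$source <- "sim"

    n_early <- round(config$frac_early_only * n)
    n_late <- round(config$frac_late_only * n)
    idx <- sample.int(n, n_early + n_late)
    class <- rep("static", n)
    class[idx[seq_len(n_early)]] <- "early_only"
    class[idx[n_early + seq_len(n_late)]] <- "late_only"

    # every region carries a baseline occupancy of depth_mean expected
    # tags; dynamic regions gain 2^planted_log2fc-fold binding in their
    # bound phase
    hi <- config$depth_mean * 2^config$planted_log2fc
    mu <- cbind(
      mu_t1 = ifelse(class == "early_only", hi, config$depth_mean),
      mu_t2 = ifelse(class == "early_only", hi, config$depth_mean),
      mu_t3 = ifelse(class == "late_only", hi, config$depth_mean),
      mu_t4 = ifelse(class == "late_only", hi, config$depth_mean)
    )

    n_cb <- round(config$frac_cobound * n)
    cobound <- rep(FALSE, n)
    cobound[sample.int(n, n_cb)] <- TRUE
    chrom_len <- setNames(layout$length, layout$chrom)
    partner_summit <- pmin(pmax(peaks$summit[cobound] +
                                  as.integer(round(runif(n_cb, -100, 100))),
                                25L),
                           chrom_len[peaks$chrom[cobound]] - 25L)
    partner_w <- pmax(50L, as.integer(round(
      rnorm(n_cb, config$peak_len_mean, 0.2 * config$peak_len_mean))))
    partners <- tibble(
      chrom = peaks$chrom[cobound],
      start = pmax(0L, as.integer(partner_summit - partner_w %/% 2L)),
      end = as.integer(partner_summit + partner_w - partner_w %/% 2L),
      name = sprintf("partner_%05d", seq_len(n_cb)),
      score = round(runif(n_cb, 1, 100), 2),
      strand = NA_character_,
      summit = as.integer(partner_summit),
      source = "sim2"
    )
    n_extra <- max(0L, round(n_cb / 2))
    extra <- if (n_extra > 0) {
      ec <- sample(layout$chrom, n_extra, replace = TRUE,
                   prob = layout$length)
      ew <- pmax(50L, as.integer(round(
        rnorm(n_extra, config$peak_len_mean, 0.2 * config$peak_len_mean))))
      es <- as.integer(floor(runif(n_extra) * (chrom_len[ec] - ew)))
      tibble(chrom = ec, start = es, end = as.integer(es + ew),
             name = sprintf("extra_%05d", seq_len(n_extra)),
             score = round(runif(n_extra, 1, 100), 2),
             strand = NA_character_,
             summit = as.integer(es + ew %/% 2L), source = "sim2")
    } else {
      NULL
    }
    second_factor <- bind_rows(partners, extra) |>
      arrange(.data$chrom, .data$start, .data$end)

    truth <- bind_cols(peaks, as_tibble(mu))
    truth$class <- class
    truth$cobound <- cobound
    truth <- arrange(truth, .data$chrom, .data$start, .data$end)

    present <- list(
      t1 = truth$class != "late_only", t2 = truth$class != "late_only",
      t3 = truth$class != "early_only", t4 = truth$class != "early_only"
    )
    peak_sets <- map(present, function(sel) {
      as_peaks(truth[sel, c("chrom", "start", "end", "name", "score",
                            "strand", "summit", "source")])
    })
    list(truth = truth, peak_sets = peak_sets,
         second_factor = second_factor)
  })
}

#' Draw an NB count matrix from per-condition expected means
#'
#' Counts are NB with variance `mean + dispersion * mean^2` (Poisson when
#' `dispersion = 0`); per-sample library-size multipliers scale the means.
#'
#' @param mu Numeric matrix features x conditions of expected means
#'   (column names are condition labels).
#' @param design Tibble with `sample_id`, `condition`, `replicate` and
#'   optionally `size_factor` (default 1).
#' @param dispersion NB dispersion (default 0.1).
#' @param seed Integer seed.
#' @return A [count_matrix()].
#' @export
sim_counts <- function(mu, design, dispersion = 0.1, seed = 1L) {
  stopifnot(is.matrix(mu), all(design$condition %in% colnames(mu)))
  if (any(mu < 0)) abort("negative expected means")
  if (!"size_factor" %in% names(design)) design$size_factor <- 1
  withr::with_seed(seed, {
    counts <- vapply(seq_len(nrow(design)), function(j) {
      m <- mu[, design$condition[j]] * design$size_factor[j]
      if (dispersion == 0) {
        as.numeric(rpois(length(m), m))
      } else {
        rnbinom(length(m), mu = m, size = 1 / dispersion)
      }
    }, numeric(nrow(mu)))
    counts <- matrix(counts, nrow = nrow(mu),
                     dimnames = list(rownames(mu), design$sample_id))
    count_matrix(counts, design[c("sample_id", "condition", "replicate")])
  })
}

#' Scatter tag positions around peak summits
#'
#' Per-peak tag counts are Poisson with the given mean; positions are
#' normal around the summit. A convenience surface for testing interval
#' counting and summit-centered signal matrices.
#'
#' @param peaks Peak tibble with summits.
#' @param mean_tags Expected tags per peak (scalar or per-peak).
#' @param spread Positional standard deviation in bp (default 50).
#' @param sample_id Sample label.
#' @param layout Genome layout tibble (positions are clamped inside).
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `chrom`, `pos`, `strand`.
#' @export
sim_tags <- function(peaks, mean_tags = 50, spread = 50,
                     sample_id = "s1", layout = NULL, seed = 1L) {
  peaks <- as_peaks(peaks)
  mean_tags <- rep_len(mean_tags, nrow(peaks))
  withr::with_seed(seed, {
    n <- rpois(nrow(peaks), mean_tags)
    pos <- unlist(map(seq_len(nrow(peaks)), function(i) {
      as.integer(round(rnorm(n[i], peaks$summit[i], spread)))
    }))
    chrom <- rep(peaks$chrom, n)
    if (!is.null(layout)) {
      maxlen <- setNames(layout$length, layout$chrom)[chrom]
      pos <- pmin(pmax(pos, 0L), maxlen - 1L)
    } else {
      pos <- pmax(pos, 0L)
    }
    tibble(sample_id = sample_id, chrom = chrom, pos = pos,
           strand = sample(c("+", "-"), length(pos), replace = TRUE))
  })
}

#' Plant exact consensus motif instances near peak summits
#'
#' With probability `rate` per peak, the consensus string replaces the
#' sequence at the summit plus a uniform(0, 50) bp offset on a random side.
#' The planted positions are returned as ground truth.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param peaks Peak tibble with summits.
#' @param consensus Consensus string (default the CACCTG E-box).
#' @param rate Per-peak plant probability (default from study conditions:
#'   0.4).
#' @param max_offset Maximum |offset| from the summit (default 50).
#' @param seed Integer seed.
#' @return List with `seqs` (modified sequences) and `planted` (tibble
#'   `peak_id`, `chrom`, `position`).
#' @export
sim_plant_motifs <- function(seqs, peaks, consensus = "CACCTG", rate = 0.4,
                             max_offset = 50L, seed = 1L) {
  peaks <- as_peaks(peaks)
  L <- nchar(consensus)
  withr::with_seed(seed, {
    plant <- runif(nrow(peaks)) < rate
    # the full motif stays within [summit - max_offset, summit + max_offset)
    offset <- as.integer(floor(runif(nrow(peaks), -max_offset,
                                     max_offset - L + 1L)))
    pos <- peaks$summit + offset
    planted <- list()
    for (i in which(plant)) {
      chr <- peaks$chrom[i]
      p <- min(max(pos[i], 0L), nchar(seqs[[chr]]) - L)
      substr(seqs[[chr]], p + 1L, p + L) <- consensus
      planted[[length(planted) + 1L]] <-
        tibble(peak_id = interval_ids(peaks)[i], chrom = chr, position = p)
    }
    list(seqs = seqs, planted = bind_rows(planted))
  })
}

#' Generate a replicated screen plate table with planted enhancers
#'
#' Negative-control and null-construct wells draw their differentiation
#' fraction from a truncated Normal(control mean, control sd); planted
#' enhancers are shifted upward so that both the z-shift
#' (`planted_effect_sd_units` control sds) and the target fold change
#' (`planted_fc`) are realized:
#' `mean = min(0.99, max(control_mean * planted_fc,
#' control_mean + units * sd))`.
#'
#' @param screen A [screen_config()] list.
#' @param seed Integer seed.
#' @return List with `table` (per-well screen tibble) and `truth`
#'   (character vector of planted construct ids).
#' @export
sim_screen <- function(screen = screen_config(), seed = 1L) {
  s <- screen
  if (s$control_pdc_mean - 4 * s$control_pdc_sd < 0 ||
      s$control_pdc_mean + 4 * s$control_pdc_sd > 1) {
    warn("control PDC within 4 sd of [0,1] bounds: truncation will bias the control distribution")
  }
  withr::with_seed(seed, {
    construct_ids <- sprintf("tf_%04d", seq_len(s$n_constructs))
    hit_ids <- if (s$n_planted > 0) {
      sample(construct_ids, s$n_planted)
    } else {
      character(0)
    }
    hit_mean <- min(0.99, max(s$control_pdc_mean * s$planted_fc,
                              s$control_pdc_mean +
                                s$planted_effect_sd_units * s$control_pdc_sd))
    rows <- map_dfr(seq_len(s$n_replicates), function(r) {
      ctrl <- tibble(
        construct_id = sprintf("neg_ctrl_%02d", seq_len(s$n_neg_controls)),
        is_negative_control = TRUE,
        mu = s$control_pdc_mean
      )
      tfs <- tibble(
        construct_id = construct_ids,
        is_negative_control = FALSE,
        mu = ifelse(construct_ids %in% hit_ids, hit_mean,
                    s$control_pdc_mean)
      )
      wells <- bind_rows(ctrl, tfs)
      wells$replicate <- r
      wells$pdc <- pmin(pmax(
        rnorm(nrow(wells), wells$mu, s$control_pdc_sd), 0), 1)
      wells
    })
    rows$plate <- sprintf("P%02d", rows$replicate)
    rows$well <- sprintf("W%04d", stats::ave(
      seq_len(nrow(rows)), rows$replicate, FUN = seq_along))
    rows$n_total_cells <- sample(800:1200, nrow(rows), replace = TRUE)
    rows$n_diff_cells <- pmin(
      as.integer(round(rows$pdc * rows$n_total_cells)), rows$n_total_cells)
    table <- rows[c("plate", "well", "construct_id", "replicate",
                    "n_total_cells", "n_diff_cells",
                    "is_negative_control")]
    list(table = validate_screen_table(table), truth = sort(hit_ids))
  })
}
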