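#' Construct a count matrix with sample metadata
#'
#' Container pairing a non-negative integer matrix (features x samples) with
#' a sample metadata tibble. The metadata must have `sample_id`, `condition`
#' and `replicate` columns covering every matrix column.
#'
#' @param counts Numeric matrix, features in rows, samples in columns;
#'   entries must be non-negative.
#' @param samples Tibble with `sample_id`, `condition`, `replicate`.
#' @return An object of class `count_matrix` with elements `counts` and
#'   `samples`.
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) abort("counts must be non-negative")
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "condition", "replicate") %in% names(samples)))
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!setequal(colnames(counts), samples$sample_id) ||
      ncol(counts) != nrow(samples)) {
    abort("sample metadata must cover exactly the matrix columns")
  }
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%05d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples (conditions: ",
      paste(unique(x$samples$condition), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Tidy a count matrix into long form
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A tibble with `feature_id`, `sample_id`, `count` plus the sample
#'   metadata columns.
#' @export
tidy.count_matrix <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "feature_id")
  long <- tidyr::pivot_longer(long, -"feature_id",
                              names_to = "sample_id", values_to = "count")
  left_join(long, x$samples, by = "sample_id")
}

#' Count tag positions falling in genomic intervals
#'
#' A tag is assigned to every interval containing its position (so
#' overlapping intervals each receive it).
#'
#' @param tags Tibble with `sample_id`, `chrom`, `pos` (0-based position) and
#'   optionally `strand`.
#' @param intervals Peak tibble (`chrom`, `start`, `end`, ...).
#' @param samples Optional sample metadata tibble; derived from `tags` when
#'   absent (condition = sample_id, replicate = 1).
#' @return A `count_matrix` of dimension |intervals| x |samples|.
#' @export
count_tags_in_intervals <- function(tags, intervals, samples = NULL) {
  intervals <- as_peaks(intervals)
  ids <- interval_ids(intervals)
  sample_ids <- if (is.null(samples)) unique(tags$sample_id) else samples$sample_id
  gr <- peaks_to_gr(intervals)
  counts <- vapply(sample_ids, function(s) {
    tg <- tags[tags$sample_id == s, , drop = FALSE]
    if (nrow(tg) == 0L) return(integer(length(gr)))
    tgr <- GenomicRanges::GRanges(tg$chrom,
                                  IRanges::IRanges(tg$pos + 1L, width = 1L))
    GenomicRanges::countOverlaps(gr, tgr)
  }, integer(length(gr)))
  counts <- matrix(counts, nrow = length(gr),
                   dimnames = list(ids, sample_ids))
  if (is.null(samples)) {
    samples <- tibble(sample_id = sample_ids, condition = sample_ids,
                      replicate = 1L)
  }
  count_matrix(counts, samples)
}

#' Estimate size factors by the median-of-ratios method
#'
#' For each feature with all-positive counts, the per-sample ratio to the
#' feature's geometric mean is formed; the size factor of a sample is the
#' median of these ratios. Features containing any zero are excluded from
#' the median.
#'
#' @param x A `count_matrix` or plain counts matrix.
#' @return Named numeric vector of per-sample size factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
#' estimate_size_factors(m)  # c(1/sqrt(2), sqrt(2))
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  stopifnot(is.matrix(counts))
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    abort(paste0("no feature has all-positive counts; size factors cannot be",
                 " estimated by median-of-ratios (consider adding a",
                 " pseudo-reference or filtering samples)"))
  }
  sf <- apply(counts[usable, , drop = FALSE], 2, function(cnts) {
    exp(median(log(cnts) - log_geo[usable]))
  })
  setNames(sf, colnames(counts))
}

#' Negative-binomial differential test between two conditions
#'
#' Re-implementation of the classic exact-style NB count test: counts are
#' normalized by median-of-ratios size factors; per-feature dispersions are
#' estimated by method-of-moments within conditions and shrunk toward a
#' mean-dispersion trend fitted across all features; the two-sided p-value
#' sums the probabilities of all allocations of the pooled count between the
#' two condition sums that are no more likely than the observed one, under
#' NB laws for each sum. p-values are BH-adjusted.
#'
#' With fewer than two replicates in every condition the dispersion is
#' estimated treating all samples as one group (a logged, conservative
#' fallback matching designs where adjacent time points stand in as
#' replicates).
#'
#' @param x A `count_matrix`.
#' @param cond_a,cond_b Condition labels in `x$samples$condition`; fold
#'   changes are reported as B vs A.
#' @param size_factors Optional pre-computed size factors (named by sample).
#' @param dispersion Optional known dispersion (scalar or per-feature),
#'   bypassing estimation; `0` gives a Poisson test.
#' @param pseudocount Added to both condition means when either is zero
#'   before forming the fold change (default 0.5 normalized counts).
#' @return A tibble of class `nb_diff_result` with `feature_id`, `base_mean`,
#'   `mean_a`, `mean_b`, `dispersion`, `fc` (B/A), `log2fc`, `p`, `padj` and
#'   `class` (`"ns"` or `"untested"` for all-zero features; see
#'   [classify_de()] to label up/down calls).
#' @export
nb_diff_test <- function(x, cond_a, cond_b, size_factors = NULL,
                         dispersion = NULL, pseudocount = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  cond <- x$samples$condition
  idx_a <- which(cond == cond_a)
  idx_b <- which(cond == cond_b)
  if (length(idx_a) < 1L || length(idx_b) < 1L) {
    abort("each condition needs at least one sample")
  }
  counts <- x$counts[, c(idx_a, idx_b), drop = FALSE]
  grp <- rep(c("A", "B"), c(length(idx_a), length(idx_b)))
  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(counts)
  } else {
    size_factors <- size_factors[colnames(counts)]
  }
  stopifnot(all(size_factors > 0))
  norm <- sweep(counts, 2, size_factors, "/")
  mean_a <- rowMeans(norm[, grp == "A", drop = FALSE])
  mean_b <- rowMeans(norm[, grp == "B", drop = FALSE])
  base_mean <- rowMeans(norm)
  tested <- base_mean > 0

  if (is.null(dispersion)) {
    disp <- estimate_dispersions(norm, grp, size_factors, base_mean)
  } else {
    disp <- rep_len(dispersion, nrow(counts))
  }

  p <- rep(NA_real_, nrow(counts))
  p[tested] <- nb_exact_p(
    k_a = rowSums(counts[tested, grp == "A", drop = FALSE]),
    k_b = rowSums(counts[tested, grp == "B", drop = FALSE]),
    q = base_mean[tested],
    sf_a = size_factors[grp == "A"],
    sf_b = size_factors[grp == "B"],
    disp = disp[tested]
  )
  padj <- p.adjust(p, method = "BH")

  num <- mean_b
  den <- mean_a
  zero <- tested & (mean_a == 0 | mean_b == 0)
  num[zero] <- num[zero] + pseudocount
  den[zero] <- den[zero] + pseudocount
  fc <- ifelse(tested, num / den, NA_real_)

  out <- tibble(
    feature_id = rownames(counts),
    base_mean = unname(base_mean),
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    dispersion = unname(disp),
    fc = unname(fc),
    log2fc = unname(log2(fc)),
    p = unname(p),
    padj = unname(padj),
    class = unname(ifelse(tested, "ns", "untested"))
  )
  class(out) <- c("nb_diff_result", class(out))
  attr(out, "conditions") <- c(A = cond_a, B = cond_b)
  out
}

# Method-of-moments dispersion per feature, shrunk toward a trend
# a(m) = a0 + a1/m fitted across features. Residual d.f. weight the
# per-feature estimate against the trend.
estimate_dispersions <- function(norm, grp, size_factors, base_mean) {
  n_rep <- table(grp)
  xi <- mean(1 / size_factors)
  if (any(n_rep >= 2L)) {
    use <- names(n_rep)[n_rep >= 2L]
    # per-condition moment estimates (variance and squared mean must come
    # from the same condition, otherwise differential features inflate),
    # pooled with d.f. weights
    mom_num <- 0
    df <- 0L
    for (g in use) {
      sel <- grp == g
      v_g <- apply(norm[, sel, drop = FALSE], 1, var)
      m_g <- rowMeans(norm[, sel, drop = FALSE])
      mom_g <- (v_g - xi * m_g) / m_g^2
      mom_g[!is.finite(mom_g)] <- NA_real_
      mom_num <- mom_num + (sum(sel) - 1L) * mom_g
      df <- df + (sum(sel) - 1L)
    }
    mom <- mom_num / df
    m <- rowMeans(norm[, grp %in% use, drop = FALSE])
  } else {
    warn("no condition has >= 2 replicates; estimating dispersion across all samples pooled")
    w <- apply(norm, 1, var)
    df <- ncol(norm) - 1L
    m <- base_mean
    mom <- (w - xi * m) / m^2
    mom[!is.finite(mom)] <- NA_real_
  }
  ok <- !is.na(mom) & m > 0
  trend <- fit_dispersion_trend(mom[ok], m[ok])
  trend_all <- pmax(trend$a0 + trend$a1 / pmax(base_mean, 1e-8), 1e-8)
  raw <- pmax(mom, 0)
  raw[is.na(raw)] <- 0
  # empirical-Bayes pull toward the trend on the log scale. The sampling
  # variance of log alpha-hat by the delta method is about
  # (2/df) * (v / (alpha m^2))^2 with v = xi m + alpha m^2: the shot-noise
  # subtraction amplifies the variance-estimator noise at low counts.
  # Spread of the log moment estimates around the trend in excess of that
  # reflects true dispersion heterogeneity and sets the prior width
  # (floored to keep some per-feature signal).
  mm <- pmax(m, 1e-8)
  samp_var <- trigamma(df / 2) * (1 + xi / (trend_all * mm))^2
  # log of a variance estimate is biased down by digamma(df/2) - log(df/2)
  log_bias <- log(df / 2) - digamma(df / 2)
  log_raw <- log(pmax(raw, trend_all / 100)) + log_bias
  pos <- raw > 0 & is.finite(trend_all) & m > 0
  excess <- if (sum(pos) >= 10L) {
    max(var(log_raw[pos] - log(trend_all[pos])) - mean(samp_var[pos]),
        0.02)
  } else {
    0.25
  }
  w_trend <- samp_var / (samp_var + excess)
  shrunk <- exp(w_trend * log(trend_all) + (1 - w_trend) * log_raw)
  shrunk[raw <= 0] <- trend_all[raw <= 0]
  pmax(shrunk, 1e-8)
}

fit_dispersion_trend <- function(mom, m) {
  keep <- mom > 0
  if (sum(keep) < 10L) {
    return(list(a0 = max(mean(pmax(mom, 0)), 1e-4), a1 = 0))
  }
  fit <- lm(mom[keep] ~ I(1 / m[keep]))
  a <- coef(fit)
  list(a0 = max(unname(a[1]), 0), a1 = max(unname(a[2]), 0))
}

# Exact-style two-sided NB p-value on condition sums. Vectorized over
# features; each feature enumerates allocations of the pooled count.
nb_exact_p <- function(k_a, k_b, q, sf_a, sf_b, disp) {
  s_a <- sum(sf_a); s_b <- sum(sf_b)
  s2_a <- sum(sf_a^2); s2_b <- sum(sf_b^2)
  vapply(seq_along(k_a), function(i) {
    mu_a <- q[i] * s_a
    mu_b <- q[i] * s_b
    var_a <- mu_a + disp[i] * q[i]^2 * s2_a
    var_b <- mu_b + disp[i] * q[i]^2 * s2_b
    k <- k_a[i] + k_b[i]
    a <- 0:k
    pa <- nb_dens(a, mu_a, var_a)
    pb <- nb_dens(k - a, mu_b, var_b)
    pr <- pa * pb
    tot <- sum(pr)
    if (tot <= 0) return(1)
    obs <- pr[k_a[i] + 1L]
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]) / tot)
  }, numeric(1))
}

nb_dens <- function(x, mu, v) {
  if (v <= mu * (1 + 1e-10)) {
    dpois(x, lambda = mu)
  } else {
    size <- mu^2 / (v - mu)
    dnbinom(x, mu = mu, size = size)
  }
}

#' Classify differential-expression results
#'
#' Labels features `up` (fold change at least `fc_up` and `padj` at most
#' `alpha`), `down` (fold change at most `fc_down`) or `ns`; all-zero
#' features stay `untested`. Bounds are inclusive.
#'
#' @param results Tibble from [nb_diff_test()].
#' @param fc_up Up-regulation fold-change threshold (default 1.5).
#' @param fc_down Down-regulation fold-change threshold (default 0.67).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return `results` with its `class` column set to
#'   `up`/`down`/`ns`/`untested`.
#' @export
classify_de <- function(results, fc_up = 1.5, fc_down = 0.67, alpha = 0.01) {
  cls <- results$class
  tested <- cls != "untested"
  up <- tested & results$fc >= fc_up & results$padj <= alpha
  down <- tested & results$fc <= fc_down & results$padj <= alpha
  cls[tested] <- "ns"
  cls[up] <- "up"
  cls[down] <- "down"
  results$class <- cls
  attr(results, "thresholds") <- c(fc_up = fc_up, fc_down = fc_down,
                                   alpha = alpha)
  results
}

#' Classify dynamic binding of regions from an early-vs-late comparison
#'
#' Given NB test results comparing late (condition B) vs early (condition A)
#' read counts over bound regions, labels each region `late_only` (late/early
#' fold change at least `fc` and `padj` at most `alpha`), `early_only`
#' (early/late fold change at least `fc`), otherwise `static`.
#'
#' @param results Tibble from [nb_diff_test()] with B = late, A = early.
#' @param fc Fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.1).
#' @return `results` with an added `dynamic_class` column.
#' @export
classify_dynamic_regions <- function(results, fc = 2, alpha = 0.1) {
  tested <- results$class != "untested"
  cls <- rep("static", nrow(results))
  cls[tested & results$fc >= fc & results$padj <= alpha] <- "late_only"
  cls[tested & results$fc <= 1 / fc & results$padj <= alpha] <- "early_only"
  results$dynamic_class <- cls
  results
}

#' Assign early/late/static classes to genes from classified regions
#'
#' The overlap window of a gene is its body plus 500 bp upstream of the TSS
#' (strand-aware). A gene is `late_only_gene` if the window overlaps at
#' least one late-only region and no early-only region; `early_only_gene` if
#' it overlaps at least one early-only region; `static_only_gene` if it
#' overlaps only static regions. Genes with no region in the window receive
#' `NA`.
#'
#' @param genes Gene tibble (see [read_gene_table()]).
#' @param regions Peak tibble with a `dynamic_class` column
#'   (from [classify_dynamic_regions()] joined back to coordinates, or a
#'   truth table).
#' @param upstream Upstream extension in bp (default 500).
#' @return `genes` with an added `dynamic_gene_class` column.
#' @export
assign_gene_dynamic_class <- function(genes, regions, upstream = 500L) {
  validate_genes(genes)
  stopifnot("dynamic_class" %in% names(regions))
  win_start <- ifelse(genes$strand == "+",
                      pmax(genes$body_start - upstream, 0L), genes$body_start)
  win_end <- ifelse(genes$strand == "+",
                    genes$body_end, genes$body_end + upstream)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(win_start + 1L, win_end))
  reg <- peaks_to_gr(as_peaks(regions))
  hits <- GenomicRanges::findOverlaps(win, reg)
  cls_by_gene <- split(regions$dynamic_class[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits))
  out <- rep(NA_character_, nrow(genes))
  for (g in names(cls_by_gene)) {
    cls <- cls_by_gene[[g]]
    i <- as.integer(g)
    out[i] <- if (any(cls == "early_only")) {
      "early_only_gene"
    } else if (any(cls == "late_only")) {
      "late_only_gene"
    } else {
      "static_only_gene"
    }
  }
  genes$dynamic_gene_class <- out
  genes
}

#' Call a region expressed from RNA polymerase II tag density
#'
#' A region counts as transcribed when its tag density reaches `threshold`
#' tags per 500 bp (inclusive).
#'
#' @param tag_count Tag count(s) over the region(s).
#' @param region_len Region length(s) in bp.
#' @param threshold Tags per 500 bp (default 10).
#' @return Logical vector.
#' @export
#' @examples
#' expressed_by_polII(c(12, 9, 10), 500)  # TRUE FALSE TRUE
expressed_by_polII <- function(tag_count, region_len, threshold = 10) {
  stopifnot(all(region_len > 0))
  tag_count / (region_len / 500) >= threshold
}

#' Per-cluster enrichment of up/down-regulated genes
#'
#' For every cluster and direction, a 2x2 table (in cluster vs not, in
#' direction vs not) is tested with a continuity-corrected chi-square;
#' when any expected cell is below 5 the test falls back to Fisher's exact
#' test and the row is flagged.
#'
#' @param gene_classes Tibble with `gene_id` and `class`
#'   (`up`/`down`/`ns`/...).
#' @param clusters Tibble with `gene_id` and `cluster`.
#' @param directions Directions to test (default `c("up", "down")`).
#' @return Tibble with one row per (cluster, direction): observed and
#'   expected in-cluster counts, fold, `p`, and `method`.
#' @export
cluster_enrichment <- function(gene_classes, clusters,
                               directions = c("up", "down")) {
  tb <- inner_join(gene_classes, clusters, by = "gene_id")
  out <- list()
  for (cl in unique(tb$cluster)) {
    for (dir in directions) {
      in_cl <- tb$cluster == cl
      in_dir <- tb$class == dir
      tab <- matrix(c(sum(in_cl & in_dir), sum(in_cl & !in_dir),
                      sum(!in_cl & in_dir), sum(!in_cl & !in_dir)),
                    nrow = 2, byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- fisher.test(tab)$p.value
        method <- "fisher"
      } else {
        p <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
        method <- "chisq"
      }
      exp_in <- expected[1, 1]
      out[[length(out) + 1L]] <- tibble(
        cluster = cl, direction = dir,
        observed = tab[1, 1], expected = exp_in,
        fold = tab[1, 1] / exp_in, p = p, method = method
      )
    }
  }
  bind_rows(out)
}

#' Compare fold changes of two regulator gene sets
#'
#' Two-sided Wilcoxon rank-sum test comparing per-gene fold changes between a
#' positive- and a negative-regulator set. Exact enumeration is used when
#' both sets have at most 8 genes and no ties; the normal approximation with
#' continuity and tie correction otherwise.
#'
#' @param fc_by_gene Tibble with `gene_id` and `fc`.
#' @param positive_set,negative_set Character vectors of gene ids.
#' @return One-row tibble: set sizes, medians, `p`, method.
#' @export
compare_regulator_sets <- function(fc_by_gene, positive_set, negative_set) {
  xs <- fc_by_gene$fc[fc_by_gene$gene_id %in% positive_set]
  ys <- fc_by_gene$fc[fc_by_gene$gene_id %in% negative_set]
  if (length(xs) == 0L) {
    abort(paste0("no measured genes in positive set; missing: ",
                 paste(head(setdiff(positive_set, fc_by_gene$gene_id), 10),
                       collapse = ", ")))
  }
  if (length(ys) == 0L) {
    abort(paste0("no measured genes in negative set; missing: ",
                 paste(head(setdiff(negative_set, fc_by_gene$gene_id), 10),
                       collapse = ", ")))
  }
  exact <- length(xs) <= 8 && length(ys) <= 8 &&
    !anyDuplicated(c(xs, ys))
  wt <- suppressWarnings(wilcox.test(xs, ys, exact = exact, correct = TRUE))
  tibble(n_positive = length(xs), n_negative = length(ys),
         median_positive = median(xs), median_negative = median(ys),
         p = wt$p.value,
         method = if (exact) "exact" else "normal_approx")
}

#' Rank or linear correlation with a p-value
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row tibble with `estimate`, `p`, `method`, `n`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined: zero variance in input")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble(estimate = unname(ct$estimate), p = ct$p.value,
         method = method, n = length(x))
}

interval_ids <- function(intervals) {
  ifelse(is.na(intervals$name) | duplicated(intervals$name),
         paste0(intervals$chrom, ":", intervals$start, "-", intervals$end),
         intervals$name)
}
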