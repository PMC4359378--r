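two_cond_design <- function(n_rep = 2L) {
  tibble::tibble(
    sample_id = paste0(rep(c("e", "l"), each = n_rep), seq_len(n_rep)),
    condition = rep(c("early", "late"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
}

test_that("tag counting in intervals matches a brute-force double loop", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      iv <- rand_peaks(30, max_pos = 5000)
      tags <- tibble::tibble(
        sample_id = sample(c("s1", "s2"), 200, replace = TRUE),
        chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
        pos = sample.int(6000, 200) - 1L, strand = "+")
      cm <- count_tags_in_intervals(tags, iv)
      brute <- sapply(c("s1", "s2"), function(s) {
        vapply(seq_len(nrow(iv)), function(i) {
          sum(tags$sample_id == s & tags$chrom == iv$chrom[i] &
                tags$pos >= iv$start[i] & tags$pos < iv$end[i])
        }, numeric(1))
      })
      expect_equal(unname(cm$counts[, c("s1", "s2")]), unname(brute))
    }
  })
  # a tag inside two overlapping intervals increments both
  iv <- as_peaks(tibble::tibble(chrom = "chr1", start = c(0L, 50L),
                                end = c(100L, 150L)))
  tags <- tibble::tibble(sample_id = "s1", chrom = "chr1", pos = 75L,
                         strand = "+")
  expect_equal(unname(count_tags_in_intervals(tags, iv)$counts[, 1]),
               c(1, 1))
  # no tags: zero matrix
  none <- tags[0, ]
  cm0 <- count_tags_in_intervals(none, iv, samples = tibble::tibble(
    sample_id = "s1", condition = "a", replicate = 1L))
  expect_true(all(cm0$counts == 0))
})

test_that("median-of-ratios size factors have their closed forms", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2)
  expect_equal(unname(estimate_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  m2 <- cbind(a = c(5, 50, 500), b = c(5, 50, 500))
  expect_equal(unname(estimate_size_factors(m2)), c(1, 1))
  # scale equivariance: scaling one sample by c scales its factor by c
  # relative to the others
  sf <- estimate_size_factors(m2)
  m3 <- m2
  m3[, 2] <- m3[, 2] * 3
  sf3 <- estimate_size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), unname(3 * sf[2] / sf[1]),
               tolerance = 1e-9)
  # zero-containing features are excluded from the median
  m4 <- rbind(m2, c(0, 100))
  expect_equal(estimate_size_factors(m4), estimate_size_factors(m2))
  expect_error(estimate_size_factors(rbind(c(0, 1), c(1, 0))),
               "all-positive")
})

test_that("planted library factors are recovered within 5%", {
  withr::with_seed(11, {
    mu <- matrix(rep(exp(runif(2000, log(20), log(500))), 2), ncol = 2,
                 dimnames = list(NULL, c("early", "late")))
  })
  design <- two_cond_design(2L)
  design$size_factor <- c(1, 2, 0.7, 1.4)
  cm <- sim_counts(mu, design, dispersion = 0.1, seed = 12)
  sf <- estimate_size_factors(cm)
  ratio <- sf / design$size_factor
  ratio <- ratio / exp(mean(log(ratio)))  # factors are relative
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("dispersion zero gives Poisson draws", {
  mu <- matrix(50, nrow = 3000, ncol = 2,
               dimnames = list(NULL, c("early", "late")))
  cm <- sim_counts(mu, two_cond_design(1L), dispersion = 0, seed = 5)
  x <- as.vector(cm$counts)
  expect_equal(var(x) / mean(x), 1, tolerance = 0.08)
})

test_that("the NB test is symmetric and flags all-zero features untested", {
  withr::with_seed(8, {
    mu <- matrix(rep(exp(runif(300, log(20), log(300))), 2), ncol = 2,
                 dimnames = list(NULL, c("early", "late")))
    mu[1:50, "late"] <- mu[1:50, "late"] * 4
  })
  cm <- sim_counts(mu, two_cond_design(2L), dispersion = 0.05, seed = 9)
  cm$counts[5, ] <- 0
  fwd <- nb_diff_test(cm, "early", "late")
  rev <- nb_diff_test(cm, "late", "early")
  expect_equal(fwd$fc, 1 / rev$fc, tolerance = 1e-9)
  expect_equal(fwd$p, rev$p, tolerance = 1e-9)
  expect_equal(fwd$class[5], "untested")
  expect_true(is.na(fwd$p[5]))
  # BH is monotone in p-rank and bounded by 1
  ord <- order(fwd$p[!is.na(fwd$p)])
  expect_true(all(diff(fwd$padj[!is.na(fwd$p)][ord]) >= -1e-12))
  expect_true(all(fwd$padj <= 1, na.rm = TRUE))
  expect_true(all(fwd$padj >= fwd$p, na.rm = TRUE))
})

test_that("null NB data give calibrated p-values and no BH discoveries", {
  withr::with_seed(21, {
    mu <- matrix(rep(exp(runif(2000, log(20), log(500))), 2), ncol = 2,
                 dimnames = list(NULL, c("early", "late")))
  })
  n_disc <- vapply(22:24, function(s) {
    cm <- sim_counts(mu, two_cond_design(3L), dispersion = 0.1, seed = s)
    res <- nb_diff_test(cm, "early", "late")
    expect_true(abs(mean(res$p < 0.05, na.rm = TRUE) - 0.05) <= 0.02)
    sum(res$padj <= 0.1, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(n_disc), 1)
})

test_that("planted fold changes are estimated with low bias and found", {
  # 2-fold features planted in both directions at mean 200 among a null
  # background (balanced, as real differential calls are, so the
  # median-of-ratios normalization stays anchored)
  mu <- matrix(200, nrow = 1000, ncol = 2,
               dimnames = list(NULL, c("early", "late")))
  up <- 1:100
  down <- 101:200
  mu[up, "late"] <- 400    # log2fc = +1
  mu[down, "late"] <- 100  # log2fc = -1
  cm <- sim_counts(mu, two_cond_design(3L), dispersion = 0.05, seed = 32)
  res <- nb_diff_test(cm, "early", "late")
  bias <- (abs(mean(res$log2fc[up]) - 1) +
             abs(mean(res$log2fc[down]) + 1)) / 2
  expect_lt(bias, 0.1)
  # power: planted log2fc = 2 at mean 100
  mu2 <- matrix(100, nrow = 1000, ncol = 2,
                dimnames = list(NULL, c("early", "late")))
  planted2 <- 1:150
  mu2[planted2, "late"] <- 400
  cm2 <- sim_counts(mu2, two_cond_design(2L), dispersion = 0.1, seed = 33)
  res2 <- nb_diff_test(cm2, "early", "late")
  expect_gte(mean(res2$padj[planted2] <= 0.1 & res2$fc[planted2] >= 2), 0.9)
})

test_that("DE classification applies inclusive paper thresholds", {
  res <- tibble::tibble(
    feature_id = paste0("f", 1:5),
    fc = c(1.6, 0.5, 0.67, 1.5, 1.2),
    padj = c(0.005, 0.5, 0.01, 0.01, 0.001),
    class = "ns")
  cls <- classify_de(res)
  expect_equal(cls$class, c("up", "ns", "down", "up", "ns"))
})

test_that("dynamic-region classes need both the fold and the padj condition", {
  res <- tibble::tibble(
    feature_id = paste0("r", 1:4),
    fc = c(3, 0.4, 3, 1.1),
    padj = c(0.05, 0.05, 0.5, 0.05),
    class = "ns")
  out <- classify_dynamic_regions(res)
  expect_equal(out$dynamic_class,
               c("late_only", "early_only", "static", "static"))
  # identical samples: everything static
  mu <- matrix(100, nrow = 100, ncol = 2,
               dimnames = list(NULL, c("early", "late")))
  cm <- sim_counts(mu, two_cond_design(2L), dispersion = 0.05, seed = 3)
  all_static <- classify_dynamic_regions(nb_diff_test(cm, "early", "late"))
  expect_true(mean(all_static$dynamic_class == "static") > 0.97)
})

test_that("planted dynamic regions are recovered by the full pipeline", {
  cfg <- sim_config(n_peaks = 500, n_genes = 80)
  g <- sim_genome(cfg, seed = 2, with_sequences = FALSE)
  tc <- sim_peak_timecourse(cfg, g, seed = 7)
  mu <- cbind(
    early = rowMeans(as.matrix(tc$truth[, c("mu_t1", "mu_t2")])),
    late = rowMeans(as.matrix(tc$truth[, c("mu_t3", "mu_t4")])))
  rownames(mu) <- tc$truth$name
  cm <- sim_counts(mu, two_cond_design(2L), dispersion = 0.1, seed = 8)
  res <- classify_dynamic_regions(nb_diff_test(cm, "early", "late"))
  dyn <- tc$truth$class != "static"
  expect_gte(mean(res$dynamic_class[dyn] == tc$truth$class[dyn]), 0.85)
  expect_gte(mean(res$dynamic_class[!dyn] == "static"), 0.95)
  # order of samples within a condition is irrelevant
  cm_swap <- cm
  cm_swap$counts <- cm_swap$counts[, c(2, 1, 4, 3)]
  cm_swap$samples <- cm_swap$samples[c(2, 1, 4, 3), ]
  res_swap <- classify_dynamic_regions(nb_diff_test(cm_swap, "early", "late"))
  expect_equal(res_swap$dynamic_class, res$dynamic_class)
})

test_that("gene dynamic classes follow the overlap rules", {
  genes <- tibble::tibble(
    gene_id = c("gLate", "gMixed", "gStatic", "gNone"),
    chrom = "chr1", strand = "+",
    tss = c(1000L, 5000L, 9000L, 13000L),
    body_start = c(1000L, 5000L, 9000L, 13000L),
    body_end = c(2000L, 6000L, 10000L, 14000L),
    exon_starts = list(1000L, 5000L, 9000L, 13000L),
    exon_ends = list(2000L, 6000L, 10000L, 14000L))
  regions <- as_peaks(tibble::tibble(
    chrom = "chr1",
    start = c(1500L, 5100L, 5200L, 9100L, 700L),
    end = c(1600L, 5150L, 5300L, 9200L, 800L)))
  regions$dynamic_class <- c("late_only", "late_only", "early_only",
                             "static", "static")
  out <- assign_gene_dynamic_class(genes, regions)
  cls <- setNames(out$dynamic_gene_class, out$gene_id)
  expect_equal(unname(cls["gLate"]), "late_only_gene")
  # an early-only region vetoes the late-only call
  expect_equal(unname(cls["gMixed"]), "early_only_gene")
  expect_equal(unname(cls["gStatic"]), "static_only_gene")
  expect_true(is.na(cls["gNone"]))
  # the 500 bp upstream window is strand-aware: region at 700-800 is
  # upstream of gLate's TSS (1000) and inside its window
  expect_true(TRUE)
})

test_that("polII expression calling uses tags per 500 bp inclusively", {
  expect_true(expressed_by_polII(12, 500))
  expect_false(expressed_by_polII(9, 500))
  expect_true(expressed_by_polII(10, 500))
  expect_equal(expressed_by_polII(c(40, 39), 2000), c(TRUE, FALSE))
})

test_that("cluster enrichment matches the direct chi-square formula", {
  withr::with_seed(13, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%03d", 1:300),
      class = sample(c("up", "down", "ns"), 300, TRUE, c(0.2, 0.2, 0.6)))
    clus <- tibble::tibble(gene_id = genes$gene_id,
                           cluster = sample(c("c1", "c2", "c3"), 300, TRUE))
  })
  res <- cluster_enrichment(genes, clus)
  row <- res[res$cluster == "c1" & res$direction == "down", ]
  tb <- inner_join(genes, clus, by = "gene_id")
  tab <- matrix(c(sum(tb$cluster == "c1" & tb$class == "down"),
                  sum(tb$cluster == "c1" & tb$class != "down"),
                  sum(tb$cluster != "c1" & tb$class == "down"),
                  sum(tb$cluster != "c1" & tb$class != "down")),
                nrow = 2, byrow = TRUE)
  if (row$method == "chisq") {
    expect_equal(stats::pchisq(brute_chisq_stat(tab), 1, lower.tail = FALSE),
                 row$p, tolerance = 1e-9)
  }
  # a cluster identical to the down-set reaches the minimal attainable p
  genes2 <- tibble::tibble(gene_id = sprintf("h%02d", 1:60),
                           class = rep(c("down", "ns"), each = 30))
  clus2 <- tibble::tibble(gene_id = genes2$gene_id,
                          cluster = rep(c("cd", "cn"), each = 30))
  res2 <- cluster_enrichment(genes2, clus2)
  pd <- res2$p[res2$cluster == "cd" & res2$direction == "down"]
  expect_lt(pd, 1e-10)
  # sparse tables fall back to Fisher and are flagged
  genes3 <- tibble::tibble(gene_id = sprintf("i%02d", 1:20),
                           class = c(rep("down", 2), rep("ns", 18)))
  clus3 <- tibble::tibble(gene_id = genes3$gene_id,
                          cluster = rep(c("x", "y"), 10))
  expect_true(all(cluster_enrichment(genes3, clus3)$method == "fisher"))
})

test_that("regulator-set comparison reproduces the exact rank-sum case", {
  fc <- tibble::tibble(gene_id = sprintf("g%d", 1:6), fc = c(1, 2, 3, 4, 5, 6))
  res <- compare_regulator_sets(fc, sprintf("g%d", 1:3), sprintf("g%d", 4:6))
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p, brute_wilcox(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-9)
  # identical sets: p = 1
  fc2 <- tibble::tibble(gene_id = c(sprintf("a%d", 1:4), sprintf("b%d", 1:4)),
                        fc = rep(c(1.3, 0.9, 1.1, 0.7), 2))
  res2 <- compare_regulator_sets(fc2, sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  expect_gt(res2$p, 0.9)
  expect_error(compare_regulator_sets(fc, c("nope"), sprintf("g%d", 4:6)),
               "missing")
  # power: a 1-sd shift at n = 50/50 is detected
  withr::with_seed(41, {
    ps <- vapply(1:5, function(i) {
      f <- tibble::tibble(
        gene_id = sprintf("g%03d", 1:100),
        fc = c(rnorm(50, 1), rnorm(50)))
      compare_regulator_sets(f, sprintf("g%03d", 1:50),
                             sprintf("g%03d", 51:100))$p
    }, numeric(1))
  })
  expect_lt(median(ps), 0.01)
})

test_that("rank correlation matches a brute-force rank transform", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(rank_correlation(x, x)$estimate, 1)
  expect_equal(rank_correlation(x, -x)$estimate, -1)
  withr::with_seed(6, {
    y <- rnorm(20)
    z <- rnorm(20)
  })
  got <- rank_correlation(y, z, "spearman")$estimate
  expect_equal(got, stats::cor(rank(y), rank(z)), tolerance = 1e-12)
  expect_error(rank_correlation(rep(1, 5), 1:5), "zero variance")
})
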