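# Quadratic brute-force oracles, kept deliberately naive and independent of
# the package's interval/scanning machinery.

rand_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                       max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len,
    name = sprintf("p%03d", seq_len(n)),
    score = runif(n, 1, 10), strand = NA_character_,
    summit = start + pmin(len - 1L, sample.int(max_len, n, TRUE) %/% 2L),
    source = "rand"
  ) |> dplyr::arrange(chrom, start, end)
}

rand_genes <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(2000, n, replace = TRUE) + 99L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    strand = strand,
    tss = ifelse(strand == "+", start, start + len - 1L),
    body_start = start, body_end = start + len,
    exon_starts = purrr::map2(start, len, ~ .x),
    exon_ends = purrr::map2(start, len, ~ .x + .y)
  )
}

# >= 1 bp intersection of half-open intervals on the same chromosome
brute_intersects <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & pmax(s1, s2) < pmin(e1, e2)
}

brute_overlap_count <- function(a, b) {
  sum(vapply(seq_len(nrow(a)), function(i) {
    any(brute_intersects(a$chrom[i], a$start[i], a$end[i],
                         b$chrom, b$start, b$end))
  }, logical(1)))
}

# gap between half-open intervals (0 when overlapping or bookended)
brute_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s2 - e1, s1 - e2))

brute_assign <- function(peaks, genes, max_dist) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- brute_gap(peaks$start[i], peaks$end[i],
                     genes$body_start[j], genes$body_end[j])
      if (d <= max_dist) {
        out[[length(out) + 1L]] <- tibble::tibble(
          peak_id = peaks$name[i], gene_id = genes$gene_id[j],
          distance = as.integer(d))
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), peak_id, gene_id)
}

brute_closest <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], ]
    if (nrow(g) == 0L) return(NA_character_)
    summit <- if (is.na(peaks$summit[i])) {
      (peaks$start[i] + peaks$end[i]) %/% 2L
    } else {
      peaks$summit[i]
    }
    d <- abs(summit - g$tss)
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

brute_annotate <- function(peaks, genes, tss_window = 500, proximal = 10000) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ch <- peaks$chrom[i]; s <- peaks$start[i]; e <- peaks$end[i]
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) > 0) {
      # TSS window: positions tss - w .. tss + w inclusive
      if (any(pmax(s, g$tss - tss_window) < pmin(e, g$tss + tss_window + 1L)))
        return("TSS")
      ex_hit <- any(vapply(seq_len(nrow(g)), function(j) {
        any(pmax(s, unlist(g$exon_starts[j])) <
              pmin(e, unlist(g$exon_ends[j])))
      }, logical(1)))
      if (ex_hit) return("exon")
      if (any(pmax(s, g$body_start) < pmin(e, g$body_end))) return("intron")
      if (any(brute_gap(s, e, g$body_start, g$body_end) <= proximal))
        return("proximal")
    }
    "distal"
  }, character(1))
}

# naive PWM scan: every window, both strands, via per-window scoring
brute_scan <- function(seq, pw, cutoff) {
  L <- pw$length
  n <- nchar(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  revcomp <- function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  rows <- list()
  if (n >= L) {
    for (p in 0:(n - L)) {
      win <- substr(seq, p + 1, p + L)
      fr <- score_window(win, pw)$score_fraction
      if (fr >= cutoff - 1e-9) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          position = p, strand = "+", fraction = fr)
      }
      fr2 <- score_window(revcomp(win), pw)$score_fraction
      if (fr2 >= cutoff - 1e-9) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          position = p, strand = "-", fraction = fr2)
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(position = integer(0), strand = character(0),
                          fraction = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(rows), position, strand)
}

# exact two-sided Fisher p by enumerating all tables with fixed margins
brute_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a) {
    dhyper(a, r1, r2, c1)
  }, numeric(1))
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumerating all assignments of ranks
brute_wilcox <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  w_obs <- sum(rank(c(x, y))[seq_len(nx)])
  combos <- utils::combn(n, nx)
  w_all <- apply(combos, 2, sum)
  mu <- nx * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# chi-square statistic with Yates continuity correction, direct formula
brute_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - e) - 0.5)^2 / e)
}

tiny_genes <- function() {
  tibble::tibble(
    gene_id = c("geneA", "geneB"),
    chrom = "chr1", strand = c("+", "-"),
    tss = c(5000L, 20999L),
    body_start = c(5000L, 18000L), body_end = c(9000L, 21000L),
    exon_starts = list(c(5000L, 7000L), c(18000L)),
    exon_ends = list(c(5500L, 7600L), c(21000L))
  )
}
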