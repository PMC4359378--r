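#' Construct a position weight matrix
#'
#' Accepts a 4 x L matrix with rows A, C, G, T. Count or probability
#' matrices (all entries non-negative, detected automatically) are converted
#' to log2-odds against a uniform background after adding a 0.25 pseudocount
#' per cell; matrices with negative entries are taken as ready log-odds.
#'
#' @param mat 4 x L numeric matrix (rows in A, C, G, T order; row names
#'   optional but checked when present).
#' @param name Motif name.
#' @return Object of class `pwm`: log-odds `mat`, per-position minima and
#'   maxima, `score_min`, `score_max`, `length`.
#' @export
pwm <- function(mat, name = "motif") {
  stopifnot(is.matrix(mat), nrow(mat) == 4, ncol(mat) >= 4,
            all(is.finite(mat)))
  if (!is.null(rownames(mat))) {
    stopifnot(identical(toupper(rownames(mat)), c("A", "C", "G", "T")))
  }
  rownames(mat) <- c("A", "C", "G", "T")
  if (all(mat >= 0)) {
    p <- sweep(mat + 0.25, 2, colSums(mat) + 1, "/")
    mat <- log2(p / 0.25)
  }
  pos_min <- apply(mat, 2, min)
  pos_max <- apply(mat, 2, max)
  score_min <- sum(pos_min)
  score_max <- sum(pos_max)
  if (score_max <= score_min) {
    abort("degenerate PWM: identical best and worst attainable scores")
  }
  structure(list(name = name, mat = mat, pos_min = pos_min,
                 pos_max = pos_max, score_min = score_min,
                 score_max = score_max, length = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ", length ", x$length,
      ", score range [", signif(x$score_min, 4), ", ",
      signif(x$score_max, 4), "]\n", sep = "")
  invisible(x)
}

#' Build a PWM from a consensus sequence
#'
#' A count matrix with `weight` counts on the consensus base at every
#' position (then converted to log-odds by [pwm()]).
#'
#' @param consensus Consensus string over ACGT.
#' @param name Motif name (defaults to the consensus).
#' @param weight Pseudo-observations per position (default 20).
#' @return A `pwm`.
#' @export
#' @examples
#' ebox <- pwm_from_consensus("CACCTG")
pwm_from_consensus <- function(consensus, name = consensus, weight = 20) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  m <- matrix(0, nrow = 4, ncol = length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- weight
  pwm(m, name = name)
}

#' The canonical E-box PWM (consensus CACCTG)
#'
#' The CACCTG-type E-box bound by ZEB-family zinc-finger/homeodomain
#' transcription factors.
#'
#' @return A `pwm`.
#' @export
ebox_pwm <- function() pwm_from_consensus("CACCTG", name = "Ebox_CACCTG")

#' Read / write a PWM file
#'
#' Tabular format: a header line `>name`, then four tab-separated rows
#' labeled A, C, G, T.
#'
#' @param path File path.
#' @return `read_pwm()`: a `pwm`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 5L, startsWith(lines[1], ">"))
  name <- sub("^>\\s*", "", lines[1])
  rows <- strsplit(lines[2:5], "\t", fixed = TRUE)
  labels <- toupper(vapply(rows, `[[`, "", 1))
  stopifnot(identical(sort(labels), c("A", "C", "G", "T")))
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- labels
  pwm(m[c("A", "C", "G", "T"), , drop = FALSE], name = name)
}

#' @param x A `pwm`.
#' @rdname read_pwm
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(paste0(">", x$name),
             vapply(rownames(x$mat), function(b) {
               paste(c(b, format(x$mat[b, ], digits = 10)), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

# Coerce DNAStringSet or character to a named character vector.
seqs_as_chr <- function(seqs) {
  if (is.character(seqs)) return(seqs)
  setNames(as.character(seqs), names(seqs))
}

# Encode a sequence as row indices into the PWM (NA for N/other).
encode_seq <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

#' Score a single window against a PWM
#'
#' The raw score is the sum of per-position log-odds; `N` (or any non-ACGT
#' base) contributes the position minimum. The score fraction rescales raw
#' scores to \[0, 1\] between the worst and best attainable score.
#'
#' @param seq_window String of length exactly `pwm$length`.
#' @param pwm A `pwm`.
#' @return One-row tibble with `score` and `score_fraction`.
#' @export
score_window <- function(seq_window, pwm) {
  code <- encode_seq(seq_window)
  stopifnot(length(code) == pwm$length)
  contrib <- vapply(seq_len(pwm$length), function(j) {
    if (is.na(code[j])) pwm$pos_min[j] else pwm$mat[code[j], j]
  }, numeric(1))
  raw <- unname(sum(contrib))
  tibble(score = raw,
         score_fraction = (raw - pwm$score_min) /
           (pwm$score_max - pwm$score_min))
}

# Vectorized forward-strand scan: score of every window start.
scan_forward <- function(code, pwm) {
  n <- length(code)
  L <- pwm$length
  if (n < L) return(numeric(0))
  n_win <- n - L + 1L
  raw <- numeric(n_win)
  for (j in seq_len(L)) {
    v <- unname(pwm$mat[, j])[code[j:(j + n_win - 1L)]]
    v[is.na(v)] <- pwm$pos_min[j]
    raw <- raw + v
  }
  unname(raw)
}

revcomp_chr <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", seq), "")[[1]]),
        collapse = "")
}

#' Scan a sequence for PWM hits above a fractional score cutoff
#'
#' Every window on the forward strand and (optionally) on the reverse
#' complement is scored; hits at or above the cutoff are reported in
#' forward coordinates, sorted by position. Overlapping hits are all kept.
#'
#' @param seq A single sequence (character or `DNAString`).
#' @param pwm A `pwm`.
#' @param cutoff Score-fraction cutoff in (0, 1\] (default 0.85).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return Tibble with `position` (0-based forward start), `strand`,
#'   `score`, `score_fraction`. Sequences shorter than the motif give an
#'   empty tibble.
#' @export
#' @examples
#' scan_sequence("TTTTTCACCTGTTTT", ebox_pwm(), cutoff = 1)
scan_sequence <- function(seq, pwm, cutoff = 0.85, both_strands = TRUE) {
  stopifnot(cutoff > 0, cutoff <= 1)
  seq <- as.character(seq)
  code <- encode_seq(seq)
  n <- length(code)
  L <- pwm$length
  rng <- pwm$score_max - pwm$score_min
  fwd <- scan_forward(code, pwm)
  out <- tibble(position = seq_along(fwd) - 1L, strand = "+",
                score = fwd)
  if (both_strands && n >= L) {
    rc <- scan_forward(encode_seq(revcomp_chr(seq)), pwm)
    out <- bind_rows(out, tibble(
      position = n - L - (seq_along(rc) - 1L), strand = "-", score = rc))
  }
  out$score_fraction <- (out$score - pwm$score_min) / rng
  out <- out[out$score_fraction >= cutoff - 1e-9, , drop = FALSE]
  arrange(out, .data$position, .data$strand)
}

#' Scan a set of sequences for PWM hits
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @inheritParams scan_sequence
#' @return Tibble with `seq_id`, `position`, `strand`, `score`,
#'   `score_fraction`.
#' @export
scan_sequences <- function(seqs, pwm, cutoff = 0.85, both_strands = TRUE) {
  seqs <- seqs_as_chr(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  map_dfr(names(seqs), function(id) {
    hits <- scan_sequence(seqs[[id]], pwm, cutoff, both_strands)
    if (nrow(hits) == 0L) return(hits)
    bind_cols(tibble(seq_id = id), hits)
  })
}

#' Fraction of peaks whose summit window contains motif hits
#'
#' Scans a `window` bp sequence centered on each peak summit and reports
#' the fraction of peaks with at least `min_hits` hits. Windows truncated
#' by a sequence end are scanned as-is and flagged.
#'
#' @param peaks Peak tibble with summits.
#' @param seqs Chromosome sequences (named character vector or
#'   `DNAStringSet`, names matching `chrom`).
#' @param pwm A `pwm`.
#' @param cutoff Score-fraction cutoff (default 0.85).
#' @param min_hits Minimum hits per peak (default 1).
#' @param window Window width in bp centered on the summit (default 100).
#' @return One-row tibble: `fraction`, `n_peaks`, `n_with_hits`,
#'   `n_truncated`, plus `min_hits` and `cutoff`.
#' @export
peaks_with_hits <- function(peaks, seqs, pwm, cutoff = 0.85, min_hits = 1L,
                            window = 100L) {
  peaks <- as_peaks(peaks)
  seqs <- seqs_as_chr(seqs)
  half <- window %/% 2L
  pos <- ifelse(is.na(peaks$summit),
                (peaks$start + peaks$end) %/% 2L, peaks$summit)
  n_trunc <- 0L
  counts <- map_int(seq_len(nrow(peaks)), function(i) {
    chr_seq <- seqs[[peaks$chrom[i]]]
    lo <- pos[i] - half
    hi <- pos[i] + half  # half-open
    if (lo < 0 || hi > nchar(chr_seq)) n_trunc <<- n_trunc + 1L
    lo <- max(lo, 0L)
    hi <- min(hi, nchar(chr_seq))
    win <- substr(chr_seq, lo + 1L, hi)
    nrow(scan_sequence(win, pwm, cutoff))
  })
  tibble(fraction = mean(counts >= min_hits), n_peaks = nrow(peaks),
         n_with_hits = sum(counts >= min_hits), n_truncated = n_trunc,
         min_hits = min_hits, cutoff = cutoff)
}

#' Motif density profile around peak summits
#'
#' Counts motif-hit starts in bins of `bin` bp relative to the summit,
#' normalized to hits per bp per peak.
#'
#' @param hits Tibble with `chrom` and `position` (absolute 0-based hit
#'   starts), e.g. from scanning chromosome sequences.
#' @param summits Peak tibble.
#' @param window Total window in bp (default 800; must be a multiple of
#'   `bin`).
#' @param bin Bin width in bp (default 10).
#' @return Tibble with `bin_start`, `bin_mid` (bp relative to summit) and
#'   `density` (hits / bp / peak).
#' @export
motif_density_profile <- function(hits, summits, window = 800L, bin = 10L) {
  stopifnot(window %% bin == 0L)
  summits <- as_peaks(summits)
  pos <- ifelse(is.na(summits$summit),
                (summits$start + summits$end) %/% 2L, summits$summit)
  half <- window %/% 2L
  edges <- seq(-half, half, by = bin)
  counts <- integer(length(edges) - 1L)
  for (chr in unique(summits$chrom)) {
    h <- hits$position[hits$chrom == chr]
    s <- pos[summits$chrom == chr]
    if (length(h) == 0L || length(s) == 0L) next
    win <- IRanges::IRanges(s - half + 1L, s + half)  # 1-based closed
    hr <- IRanges::IRanges(h + 1L, width = 1L)
    ov <- IRanges::findOverlaps(hr, win)
    rel <- h[S4Vectors::queryHits(ov)] - s[S4Vectors::subjectHits(ov)]
    idx <- pmin(pmax(floor((rel + half) / bin) + 1L, 1L),
                length(counts))
    tb <- tabulate(idx, nbins = length(counts))
    counts <- counts + tb
  }
  tibble(bin_start = edges[-length(edges)],
         bin_mid = edges[-length(edges)] + bin / 2,
         density = counts / (nrow(summits) * bin))
}
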