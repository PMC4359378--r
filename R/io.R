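#' Read a peak set from a BED6+2 file
#'
#' The on-disk dialect is BED6 plus two extra columns:
#' `chrom, start, end, name, score, strand, summit_offset, source_caller`.
#' Coordinates are 0-based half-open (BED convention) both on disk and in
#' memory. The relative `summit_offset` is resolved to an absolute `summit`
#' position on reading; missing values are encoded as `"."`.
#'
#' @param path Path to a tab-separated BED6+2 file without header.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit` (absolute position) and `source`, sorted by
#'   (`chrom`, `start`, `end`).
#' @export
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tpk1\t8.5\t.\t120\tcallerA", p)
#' read_peaks(p)
read_peaks <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warn(paste0("empty peak file: ", path))
    return(empty_peaks())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 8L)
  if (length(bad) > 0L) {
    abort(paste0("malformed BED6+2 line ", bad[1], " in ", path,
                 ": expected 8 tab-separated fields, got ",
                 lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    abort(paste0("malformed coordinates on line ", bad[1], " in ", path))
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    abort(paste0("start >= end on line ", bad[1], " in ", path))
  }
  summit_offset <- dot_na_int(m[, 7])
  summit <- ifelse(is.na(summit_offset), NA_integer_, start + summit_offset)
  bad <- which(!is.na(summit) & (summit < start | summit >= end))
  if (length(bad) > 0L) {
    abort(paste0("summit outside interval on line ", bad[1], " in ", path))
  }
  out <- tibble(
    chrom = m[, 1],
    start = start,
    end = end,
    name = dot_na_chr(m[, 4]),
    score = dot_na_dbl(m[, 5]),
    strand = dot_na_chr(m[, 6]),
    summit = as.integer(summit),
    source = dot_na_chr(m[, 8])
  )
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write a peak set to a BED6+2 file
#'
#' Inverse of [read_peaks()]: the absolute `summit` is written back as an
#' offset relative to `start`, and `NA`s become `"."`.
#'
#' @param peaks Peak tibble as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- as_peaks(peaks)
  lines <- paste(
    peaks$chrom, peaks$start, peaks$end,
    na_dot(peaks$name), na_dot(peaks$score), na_dot(peaks$strand),
    na_dot(ifelse(is.na(peaks$summit), NA_integer_, peaks$summit - peaks$start)),
    na_dot(peaks$source),
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a tabular gene model file
#'
#' Tab-separated with header:
#' `gene_id, chrom, strand, tss, body_start, body_end, exon_starts, exon_ends`,
#' where the exon columns are comma-joined coordinate lists. All coordinates
#' are 0-based half-open; `tss` is a single position coinciding with the
#' strand-appropriate edge of the gene body.
#'
#' @param path Path to the gene table.
#' @return A tibble with one row per gene; `exon_starts`/`exon_ends` are
#'   integer list-columns.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    strand = readr::col_character(), tss = readr::col_integer(),
    body_start = readr::col_integer(), body_end = readr::col_integer(),
    exon_starts = readr::col_character(), exon_ends = readr::col_character()
  ))
  tb$exon_starts <- lapply(strsplit(tb$exon_starts, ","), as.integer)
  tb$exon_ends <- lapply(strsplit(tb$exon_ends, ","), as.integer)
  validate_genes(tb)
  tb
}

#' Write a tabular gene model file
#'
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  validate_genes(genes)
  out <- genes
  out$exon_starts <- map_chr(genes$exon_starts, paste, collapse = ",")
  out$exon_ends <- map_chr(genes$exon_ends, paste, collapse = ",")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a count matrix with its sample-metadata sidecar
#'
#' The counts file is tab-separated, features in rows with a `feature_id`
#' column, one column per sample. The sidecar (default `<path>.samples.tsv`)
#' has columns `sample_id`, `condition`, `replicate` and must cover every
#' sample column.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Path to the sidecar; defaults to `<path>.samples.tsv`.
#' @return A `count_matrix` object (see [count_matrix()]).
#' @export
read_counts <- function(path, meta_path = paste0(path, ".samples.tsv")) {
  stopifnot(file.exists(path), file.exists(meta_path))
  tb <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()
  ))
  counts <- as.matrix(tb[, setdiff(names(tb), "feature_id"), drop = FALSE])
  rownames(counts) <- tb$feature_id
  samples <- readr::read_tsv(meta_path, col_types = readr::cols(
    sample_id = readr::col_character(), condition = readr::col_character(),
    replicate = readr::col_integer()
  ))
  count_matrix(counts, samples)
}

#' Write a count matrix and its sample-metadata sidecar
#'
#' @param x A `count_matrix`.
#' @param path Output path for the counts TSV; the sidecar goes to
#'   `<path>.samples.tsv`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  tb <- bind_cols(tibble(feature_id = rownames(x$counts)),
                  as_tibble(x$counts))
  readr::write_tsv(tb, path)
  readr::write_tsv(x$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' Read a per-well screen table
#'
#' Tab-separated with header: `plate, well, construct_id, replicate,
#' n_total_cells, n_diff_cells, is_negative_control`.
#'
#' @param path Path to the screen table.
#' @return A tibble, one row per well.
#' @export
read_screen_table <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_tsv(path, col_types = readr::cols(
    plate = readr::col_character(), well = readr::col_character(),
    construct_id = readr::col_character(), replicate = readr::col_integer(),
    n_total_cells = readr::col_integer(), n_diff_cells = readr::col_integer(),
    is_negative_control = readr::col_logical()
  ))
  validate_screen_table(tb)
  tb
}

#' Write a per-well screen table
#'
#' @param table Screen tibble as returned by [read_screen_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(table, path) {
  validate_screen_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read / write a gene set (one identifier per line)
#'
#' @param path File path.
#' @return `read_gene_set()`: a character vector of unique ids.
#' @export
read_gene_set <- function(path) {
  stopifnot(file.exists(path))
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' @param ids Character vector of gene ids.
#' @rdname read_gene_set
#' @export
write_gene_set <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around Biostrings keeping the rest of the package free of
#' direct format handling.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @param seqs A named `DNAStringSet` or named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ---- internal helpers --------------------------------------------------

empty_peaks <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         name = character(), score = double(), strand = character(),
         summit = integer(), source = character())
}

#' Coerce and validate a peak tibble
#'
#' Ensures the standard peak columns (`chrom`, `start`, `end`, `name`,
#' `score`, `strand`, `summit`, `source`) are present (filling optional ones
#' with `NA`), that `start < end`, and that summits lie inside their
#' intervals. All peak-consuming functions accept anything this function
#' accepts.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return A peak tibble with the full column set.
#' @export
as_peaks <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("peak table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  for (col in c("name", "strand", "source")) {
    if (is.null(x[[col]])) x[[col]] <- NA_character_
  }
  if (is.null(x[["score"]])) x[["score"]] <- NA_real_
  if (is.null(x[["summit"]])) x[["summit"]] <- NA_integer_
  stopifnot(all(x$start < x$end))
  ok <- is.na(x$summit) | (x$summit >= x$start & x$summit < x$end)
  if (!all(ok)) abort("summit outside its interval")
  x[c("chrom", "start", "end", "name", "score", "strand", "summit", "source")]
}

validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "body_start", "body_end",
            "exon_starts", "exon_ends")
  stopifnot(all(need %in% names(genes)))
  stopifnot(all(genes$strand %in% c("+", "-")))
  stopifnot(all(genes$body_start < genes$body_end))
  edge <- ifelse(genes$strand == "+", genes$body_start, genes$body_end - 1L)
  if (!all(genes$tss == edge)) {
    abort("tss must coincide with the strand-appropriate gene body edge")
  }
  ok <- map2(genes$exon_starts, genes$exon_ends, function(s, e) {
    length(s) == length(e) && all(s < e) &&
      (length(s) < 2L || all(s[-1] >= e[-length(e)]))
  })
  if (!all(unlist(ok))) abort("exons must be disjoint, sorted, start < end")
  invisible(genes)
}

validate_screen_table <- function(tb) {
  need <- c("plate", "well", "construct_id", "replicate",
            "n_total_cells", "n_diff_cells", "is_negative_control")
  stopifnot(all(need %in% names(tb)))
  stopifnot(all(tb$n_total_cells > 0L),
            all(tb$n_diff_cells >= 0L),
            all(tb$n_diff_cells <= tb$n_total_cells))
  invisible(tb)
}

dot_na_chr <- function(x) ifelse(x == ".", NA_character_, x)
dot_na_int <- function(x) suppressWarnings(as.integer(ifelse(x == ".", NA, x)))
dot_na_dbl <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
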