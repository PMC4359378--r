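#' MA-style plot of a differential count analysis
#'
#' Mean expression against log2 fold change, colored by class when
#' [classify_de()] (or [classify_dynamic_regions()]) has been applied.
#'
#' @param object An `nb_diff_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_diff_result <- function(object, ...) {
  df <- filter(as_tibble(object), .data$class != "untested")
  colour_col <- if ("dynamic_class" %in% names(df)) "dynamic_class" else "class"
  ggplot(df, aes(x = log10(.data$base_mean + 1), y = .data$log2fc,
                 colour = .data[[colour_col]])) +
    geom_point(size = 0.8, alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "log10 mean normalized count", y = "log2 fold change",
         colour = NULL) +
    theme_bw()
}

#' One-row summary of a differential count analysis
#'
#' @param x An `nb_diff_result` tibble.
#' @param ... Unused.
#' @return One-row tibble: features tested, class counts, conditions.
#' @export
glance.nb_diff_result <- function(x, ...) {
  cond <- attr(x, "conditions")
  tibble(
    n_features = nrow(x),
    n_tested = sum(x$class != "untested"),
    n_up = sum(x$class == "up"),
    n_down = sum(x$class == "down"),
    condition_a = cond[["A"]],
    condition_b = cond[["B"]]
  )
}

#' Heatmap of a summit-centered signal matrix
#'
#' @param object A `signal_matrix` (see [summit_signal_matrix()]).
#' @param sample Sample id to display (default first).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signal_matrix <- function(object, sample = NULL, ...) {
  if (is.null(sample)) sample <- names(object$matrices)[1]
  m <- object$matrices[[sample]]
  half <- object$window / 2
  df <- tidyr::expand_grid(row = seq_len(nrow(m)),
                           bin = seq_len(ncol(m))) |>
    mutate(pos = (.data$bin - 0.5) * object$bin - half,
           signal = as.vector(t(m)))
  ggplot(df, aes(x = .data$pos, y = .data$row, fill = .data$signal)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkblue") +
    labs(x = "distance from summit (bp)", y = "regions (ranked)",
         fill = "log2 signal", title = sample) +
    theme_bw()
}

#' Plot a motif density profile
#'
#' @param profile Tibble from [motif_density_profile()].
#' @return A ggplot.
#' @export
plot_motif_density <- function(profile) {
  ggplot(profile, aes(x = .data$bin_mid, y = .data$density)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "distance from summit (bp)", y = "motif hits / bp / peak") +
    theme_bw()
}

#' Bar plot of peak annotation categories
#'
#' @param peaks Annotated peak tibble (from [annotate_peaks()]).
#' @return A ggplot.
#' @export
plot_annotation_categories <- function(peaks) {
  stopifnot("annotation" %in% names(peaks))
  df <- count(peaks, .data$annotation)
  ggplot(df, aes(x = .data$annotation, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "peaks") +
    theme_bw()
}

#' @export
print.signal_matrix <- function(x, ...) {
  m <- x$matrices[[1]]
  cat("<signal_matrix> ", length(x$matrices), " sample(s), ",
      nrow(m), " regions x ", ncol(m), " bins of ", x$bin, " bp\n", sep = "")
  invisible(x)
}
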