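#' Percentage of differentiated cells per well
#'
#' The differentiation readout of a well is the number of cells with at
#' least four lipid droplets divided by the total number of cells.
#'
#' @param n_diff_cells Differentiated cell count(s).
#' @param n_total_cells Total cell count(s); must be positive.
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' compute_pdc(479, 1000)  # 0.479
compute_pdc <- function(n_diff_cells, n_total_cells) {
  if (any(n_total_cells <= 0)) abort("empty well: n_total_cells must be > 0")
  stopifnot(all(n_diff_cells >= 0), all(n_diff_cells <= n_total_cells))
  n_diff_cells / n_total_cells
}

#' Count differentiated cells from per-cell droplet counts
#'
#' @param droplet_counts Integer vector of lipid-droplet counts per cell.
#' @param min_droplets Differentiation threshold (default 4, inclusive).
#' @return Fraction of cells at or above the threshold.
#' @export
pdc_from_droplets <- function(droplet_counts, min_droplets = 4L) {
  compute_pdc(sum(droplet_counts >= min_droplets), length(droplet_counts))
}

#' Normalize well readouts to negative controls within a replicate
#'
#' The normal transform: each well's PDC is converted to a z-score against
#' the mean and standard deviation of the replicate's negative-control
#' wells.
#'
#' @param pdc Well PDC values of one replicate.
#' @param control_pdc Negative-control PDC values of the same replicate
#'   (at least 2, with positive spread).
#' @return z-scores.
#' @export
normalize_replicate <- function(pdc, control_pdc) {
  if (length(control_pdc) < 2L) {
    abort("need at least 2 negative-control wells per replicate")
  }
  s <- sd(control_pdc)
  if (s == 0) abort("negative-control wells have zero variance")
  (pdc - mean(control_pdc)) / s
}

#' Per-construct fold changes versus pooled negative controls
#'
#' `fc = mean PDC(construct wells) / mean PDC(all negative-control wells)`.
#'
#' @param table Screen tibble (see [read_screen_table()]).
#' @return Tibble with `construct_id`, `pdc_mean`, `fc`, sorted by
#'   decreasing `fc`.
#' @export
screen_fold_changes <- function(table) {
  validate_screen_table(table)
  table$pdc <- compute_pdc(table$n_diff_cells, table$n_total_cells)
  control_mean <- mean(table$pdc[table$is_negative_control])
  if (!is.finite(control_mean) || control_mean == 0) {
    abort("pooled negative-control mean PDC is zero or undefined")
  }
  table |>
    filter(!.data$is_negative_control) |>
    group_by(.data$construct_id) |>
    summarise(pdc_mean = mean(.data$pdc), .groups = "drop") |>
    mutate(fc = .data$pdc_mean / control_mean) |>
    arrange(desc(.data$fc))
}

#' Call differentiation-enhancing constructs from an arrayed screen
#'
#' Wells are scored as PDC, z-normalized to the negative controls of their
#' replicate, per-construct z-scores combined across replicates (Stouffer:
#' `mean(z) * sqrt(n_replicates)`), converted to a two-sided normal p,
#' Bonferroni-corrected over the non-control constructs, and intersected
#' with a fold-change filter: a hit satisfies `fc >= fc_threshold` and
#' Bonferroni p `<= alpha`.
#'
#' With `combine = "all-significant"` a construct is instead required to be
#' individually Bonferroni-significant in every replicate; the reported
#' `combined_p` is then the largest per-replicate p.
#'
#' @param table Screen tibble (see [read_screen_table()]).
#' @param fc_threshold Fold-change threshold (default 1.5, inclusive).
#' @param alpha Family-wise error level (default 0.05, inclusive).
#' @param combine Replicate combination rule, `"stouffer"` (default) or
#'   `"all-significant"`.
#' @return A tibble of class `screen_hits`, one row per construct sorted by
#'   decreasing fold change: `construct_id`, `n_replicates`,
#'   `complete` (present in all replicates), `pdc_mean`, `fc`, `z_combined`,
#'   `combined_p`, `p_bonferroni`, `is_hit`. Attributes carry the control
#'   mean, thresholds and number of constructs tested.
#' @export
call_screen_hits <- function(table, fc_threshold = 1.5, alpha = 0.05,
                             combine = c("stouffer", "all-significant")) {
  combine <- match.arg(combine)
  validate_screen_table(table)
  table$pdc <- compute_pdc(table$n_diff_cells, table$n_total_cells)

  reps <- unique(table$replicate)
  z_tbl <- map_dfr(reps, function(r) {
    wells <- table[table$replicate == r, ]
    ctrl <- wells$pdc[wells$is_negative_control]
    wells$z <- normalize_replicate(wells$pdc, ctrl)
    wells
  })

  constructs <- z_tbl |> filter(!.data$is_negative_control)
  n_tested <- length(unique(constructs$construct_id))
  control_mean <- mean(table$pdc[table$is_negative_control])

  per <- constructs |>
    group_by(.data$construct_id) |>
    summarise(
      n_replicates = dplyr::n_distinct(.data$replicate),
      pdc_mean = mean(.data$pdc),
      z_combined = mean(.data$z) * sqrt(dplyr::n_distinct(.data$replicate)),
      max_rep_p = max(2 * pnorm(-abs(.data$z))),
      .groups = "drop"
    ) |>
    mutate(
      complete = .data$n_replicates == length(reps),
      fc = .data$pdc_mean / control_mean,
      combined_p = if (combine == "stouffer") {
        2 * pnorm(-abs(.data$z_combined))
      } else {
        .data$max_rep_p
      },
      p_bonferroni = pmin(1, .data$combined_p * n_tested),
      is_hit = .data$fc >= fc_threshold & .data$p_bonferroni <= alpha
    ) |>
    select(-"max_rep_p") |>
    arrange(desc(.data$fc))

  if (any(!per$complete)) {
    warn(paste0(sum(!per$complete),
                " construct(s) missing from some replicate; flagged via",
                " complete = FALSE"))
  }
  structure(per,
            class = c("screen_hits", class(per)),
            control_pdc_mean = control_mean,
            n_constructs_tested = n_tested,
            fc_threshold = fc_threshold, alpha = alpha, combine = combine)
}

#' @export
tidy.screen_hits <- function(x, ...) as_tibble(x)

#' One-row summary of a screen hit-calling run
#'
#' @param x A `screen_hits` object.
#' @param ... Unused.
#' @return One-row tibble: constructs tested, hits, control PDC, thresholds.
#' @export
glance.screen_hits <- function(x, ...) {
  tibble(
    n_constructs = attr(x, "n_constructs_tested"),
    n_hits = sum(x$is_hit),
    n_fc_above_1 = sum(x$fc > 1),
    control_pdc_mean = attr(x, "control_pdc_mean"),
    fc_threshold = attr(x, "fc_threshold"),
    alpha = attr(x, "alpha"),
    combine = attr(x, "combine")
  )
}

#' Fold-change overview plot of a screen
#'
#' Constructs with fold change above 1, ranked, hits highlighted.
#'
#' @param object A `screen_hits` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.screen_hits <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(.data$fc > 1) |>
    mutate(rank = row_number())
  ggplot(df, aes(x = .data$rank, y = .data$fc, colour = .data$is_hit)) +
    geom_point(size = 1) +
    geom_hline(yintercept = attr(object, "fc_threshold"),
               linetype = "dashed") +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    labs(x = "construct rank", y = "differentiation fold change vs control",
         colour = "significant hit") +
    theme_bw()
}
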