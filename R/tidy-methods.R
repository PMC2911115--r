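# broom-style accessors and ggplot2 autoplot methods for the result types.

#' Tidy a fitted classification into its ranked target table
#'
#' @param x A `start_classification`.
#' @param ... Unused.
#' @return Tibble `rank`, `gene`, `sum` restricted to the selected targets.
#' @export
tidy.start_classification <- function(x, ...) {
  x$scores |>
    dplyr::filter(.data$rank <= x$cutoff) |>
    dplyr::select("rank", "gene", "sum")
}

#' One-row summary of a classification
#'
#' @param x A `start_classification`.
#' @param ... Unused.
#' @return One-row tibble: `tf`, `cutoff`, `n_targets`, `feasible` and the
#'   combined benchmark metrics at the cutoff.
#' @export
glance.start_classification <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(tf = x$tf %||% NA_character_, cutoff = x$cutoff,
                   n_targets = length(x$targets), feasible = x$feasible),
    x$metrics)
}

#' Tidy an LLS weight table
#'
#' @param x An `lls_weights` table.
#' @param ... Unused.
#' @return The underlying tibble plus the smoothing pseudocount column.
#' @export
tidy.lls_weights <- function(x, ...) {
  tibble::as_tibble(x) |> dplyr::mutate(pseudocount = attr(x, "pseudocount"))
}

#' Plot combined quality-metric curves along the ranked list
#'
#' @param object A `metric_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_profile <- function(object, ...) {
  long <- object |>
    dplyr::select("rank", "sensitivity", "specificity", "precision",
                  "accuracy", "mcc") |>
    tidyr::pivot_longer(-"rank", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "cutoff rank", y = "combined metric value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a classification's metric profile with its selected cutoff
#'
#' @param object A `start_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.start_classification <- function(object, ...) {
  autoplot(object$profile) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(title = sprintf("%s cutoff at rank %d (%s)",
                                  object$tf %||% "", object$cutoff,
                                  ifelse(object$feasible, "constraints met",
                                         "constraints infeasible")))
}

#' Plot a cell-cycle peak-phase histogram
#'
#' @param object A `peak_phase_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peak_phase_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_start + diff(c(.data$bin_start[1:2])) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$bin_start[1:2]) * 0.9) +
    ggplot2::labs(x = "expression peak (% of cell cycle)", y = "targets",
                  subtitle = sprintf("%d targets, %d without peak data (ND)",
                                     object$n_targets, object$n_nd)) +
    ggplot2::theme_minimal()
}

#' Plot MCC of a location dataset along the reference ranked list
#'
#' @param object A `location_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.location_benchmark <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff, y = .data$mcc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "reference cutoff rank", y = "MCC") +
    ggplot2::theme_minimal()
}

#' Plot motif zone occupancy for a target set
#'
#' @param object A `motif_position_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_position_summary <- function(object, ...) {
  occ <- object$occurrences |>
    dplyr::mutate(zone = factor(.data$zone, levels = c("proximal", "mid", "distal")))
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$zone, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("upstream zone (boundaries %s bp)",
                              paste(object$boundaries, collapse = "/")),
                  y = sprintf("fraction of %s occurrences", object$motif)) +
    ggplot2::theme_minimal()
}
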