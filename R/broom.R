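#' Tidy a surface-call result
#'
#' @param x A `surface_calls` tibble.
#' @param ... Unused.
#' @return A plain tibble, one row per protein per PDX.
#' @exportS3Method generics::tidy
tidy.surface_calls <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' One-row summary of a surface-call result
#'
#' @param x A `surface_calls` tibble.
#' @param ... Unused.
#' @return A tibble with one row per PDX: proteins tested, detections,
#'   median q-value, and the detection mode used.
#' @exportS3Method generics::glance
glance.surface_calls <- function(x, ...) {
  params <- attr(x, "call_params")
  tibble::as_tibble(unclass_result(x)) |>
    dplyr::group_by(.data$pdx_id) |>
    dplyr::summarise(
      n_proteins = dplyr::n(),
      n_detected = sum(.data$detected),
      median_q = stats::median(.data$q_value),
      mode = params$mode,
      .groups = "drop"
    )
}

#' Tidy a candidate-triage result
#'
#' @param x A `candidate_triage` table.
#' @param ... Unused.
#' @return A tibble of the final ranked candidates (cascade survivors).
#' @exportS3Method generics::tidy
tidy.candidate_triage <- function(x, ...) {
  tibble::as_tibble(unclass_result(x)) |>
    dplyr::filter(.data$not_excluded) |>
    dplyr::arrange(.data$rank)
}

#' One-row summary of a candidate-triage result
#'
#' @param x A `candidate_triage` table.
#' @param ... Unused.
#' @return A one-row tibble: the stage-count waterfall in wide form plus
#'   the number of known CAR targets among the final candidates.
#' @exportS3Method generics::glance
glance.candidate_triage <- function(x, ...) {
  wf <- attr(x, "waterfall")
  out <- tibble::as_tibble(as.list(stats::setNames(wf$n, wf$stage)))
  out$n_known_car_targets <- sum(x$known_car_target & x$not_excluded)
  out
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("surface_calls", "candidate_triage"))
  x
}
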