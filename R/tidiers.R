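#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' broom-style accessors for stridewise result objects:
#'
#' * `tidy()` returns the per-unit table (per-stride parameters, matched
#'   pairs, per-stride errors, per-item CV scores),
#' * `glance()` returns a one-row summary.
#'
#' @param x a stridewise result object.
#' @param ... unused.
#' @return a tibble.
#' @name stridewise-tidiers
NULL

#' @rdname stridewise-tidiers
#' @export
tidy.gait_analysis <- function(x, ...) x$parameters

#' @rdname stridewise-tidiers
#' @export
glance.gait_analysis <- function(x, ...) {
  p <- x$parameters
  tibble::tibble(
    n_strides = nrow(x$strides),
    n_min_vel_strides = nrow(x$min_vel_strides),
    mean_stride_time = mean(p$stride_time, na.rm = TRUE),
    mean_stride_length = mean(p$stride_length, na.rm = TRUE),
    mean_gait_velocity = mean(p$gait_velocity, na.rm = TRUE)
  )
}

#' @rdname stridewise-tidiers
#' @export
tidy.stride_matching <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$pairs, status = "tp"),
    tibble::tibble(detected_id = x$false_positives,
                   reference_id = NA_integer_, distance = NA_real_,
                   status = "fp"),
    tibble::tibble(detected_id = NA_integer_,
                   reference_id = x$false_negatives, distance = NA_real_,
                   status = "fn")
  )
}

#' @rdname stridewise-tidiers
#' @export
glance.stride_matching <- function(x, ...) precision_recall_f1(x)

#' @rdname stridewise-tidiers
#' @export
tidy.parameter_errors <- function(x, ...) x$per_stride

#' @rdname stridewise-tidiers
#' @export
glance.parameter_errors <- function(x, ...) {
  tibble::tibble(
    mean_error = mean(x$per_stride$error),
    mae = mean(x$per_stride$abs_error),
    median_ae = stats::median(x$per_stride$abs_error),
    n_strides = nrow(x$per_stride),
    n_unmatched = x$n_unmatched
  )
}

#' @rdname stridewise-tidiers
#' @export
tidy.cv_result <- function(x, ...) x$results

#' @rdname stridewise-tidiers
#' @export
glance.cv_result <- function(x, ...) {
  num <- dplyr::select(x$summary, -dplyr::all_of("fold"))
  dplyr::summarise(num, dplyr::across(dplyr::everything(), mean))
}

#' @rdname stridewise-tidiers
#' @export
tidy.kalman_result <- function(x, ...) tibble::as_tibble(x$trajectory)

#' @rdname stridewise-tidiers
#' @export
glance.kalman_result <- function(x, ...) {
  p <- traj_pos(x$trajectory)
  n <- nrow(p)
  tibble::tibble(
    n_samples = n,
    n_zupt_regions = nrow(x$zupts),
    total_displacement = sqrt(sum((p[n, 1:2] - p[1, 1:2])^2)),
    final_cov_trace = x$cov_trace_smoothed[n]
  )
}
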