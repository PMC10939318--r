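#' Stride templates
#'
#' A stride template is a short 1-D `gyr_ml` series (deg/s) representing a
#' single prototypical stride, together with its sampling rate and an
#' amplitude `scaling` divisor (deg/s) that is applied to both template and
#' signal before costing so that the accumulated DTW cost is dimensionless.
#'
#' @param samples numeric vector of gyr_ml samples (deg/s), length >= 3.
#' @param sampling_rate sampling rate in Hz.
#' @param scaling amplitude divisor in deg/s (> 0).
#' @param provenance free-text provenance string.
#' @return an object of class `stride_template`.
#' @export
stride_template <- function(samples, sampling_rate, scaling = 500,
                            provenance = "user") {
  samples <- as.numeric(samples)
  if (length(samples) < 3) stop("a stride template needs at least 3 samples")
  stopifnot(sampling_rate > 0, scaling > 0)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         scaling = scaling, provenance = provenance),
    class = "stride_template"
  )
}

#' @export
print.stride_template <- function(x, ...) {
  cat(sprintf("# stride template: %d samples @ %g Hz, scaling %g deg/s (%s)\n",
              length(x$samples), x$sampling_rate, x$scaling, x$provenance))
  invisible(x)
}

#' @rdname stride_template
#' @param path JSON file path.
#' @export
write_template_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname stride_template
#' @export
read_template_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  stride_template(p$samples, p$sampling_rate, p$scaling, p$provenance)
}

#' Default synthetic stride template
#'
#' Loads the packaged template: the `gyr_ml` trace of one noise-free
#' simulated stride at 204.8 Hz (see [simulate_session()]). The template
#' spans a full toe-off-to-toe-off stride (swing arc followed by flat
#' stance).
#'
#' @return a `stride_template`.
#' @export
default_stride_template <- function() {
  read_template_json(
    system.file("extdata", "stride_template_synthetic.json",
                package = "stridewise", mustWork = TRUE))
}

#' @rdname default_stride_template
#' @param profile gait profile used to generate the template stride.
#' @param scaling amplitude divisor in deg/s.
#' @export
synthetic_stride_template <- function(profile = gait_profile(n_strides = 3),
                                      scaling = 500) {
  bundle <- simulate_session(profile)
  body <- to_body_frame(bundle$recording, profile$side)
  s <- bundle$strides
  stride_template(
    body$gyr_ml[(s$start[1] + 1):s$end[1]],
    sampling_rate = profile$sampling_rate, scaling = scaling,
    provenance = paste0(
      "synthetic: one noise-free simulated stride (toe-off to toe-off), ",
      "default gait profile, ", profile$sampling_rate, " Hz"))
}

#' Segment strides by subsequence dynamic time warping
#'
#' Matches a stride template against a continuous 1-D signal (normally the
#' body-frame `gyr_ml` trace) with subsequence DTW: the accumulated-cost
#' matrix has a free start in the signal (first template row initialized to
#' the local cost) and step set \{diagonal, vertical, horizontal\}; local
#' cost is the squared difference of amplitude-scaled samples. Candidate
#' match ends are weak local minima of the final-row cost that fall below
#' `max_cost`; each candidate's start comes from the best warping path.
#' Overlapping candidates are resolved by keeping the lower-cost match
#' (ties: the earlier one), and matches outside the duration bounds are
#' discarded.
#'
#' With a finite `max_local_run` the same recursion is solved under a local
#' warping constraint: paths containing more than `max_local_run`
#' consecutive vertical or horizontal steps are inadmissible.
#' `max_local_run = Inf` (the default) is the unconstrained algorithm.
#'
#' The accumulated cost is *not* length-normalized, so `max_cost` scales
#' with template length.
#'
#' @param signal numeric vector sampled at the template's rate (resample
#'   beforehand otherwise).
#' @param template a [stride_template()].
#' @param max_cost acceptance threshold on the accumulated match cost.
#' @param min_match_duration,max_match_duration admissible stride duration
#'   bounds in seconds.
#' @param max_local_run maximum admissible run of consecutive non-diagonal
#'   steps; `Inf` disables the constraint.
#' @param end_tolerance hysteresis (cost units) used when locating the
#'   right edge of each final-row cost valley: the match end extends while
#'   the cost stays within `end_tolerance` of the valley minimum. This
#'   absorbs the slow cost drift that sensor noise causes over flat signal
#'   stretches; it is orders of magnitude below any real signal-shape cost
#'   increment and has no effect on noise-free signals.
#' @param resolve_overlaps if `FALSE`, overlapping candidate matches are
#'   all returned (diagnostics only; the result is then not a valid stride
#'   list).
#' @return a stride list tibble with columns `stride_id`, `start`, `end`
#'   (0-based, half-open) and `cost`.
#' @export
subsequence_dtw <- function(signal, template, max_cost = 5,
                            min_match_duration = 0.6,
                            max_match_duration = 3,
                            max_local_run = Inf,
                            end_tolerance = 1e-4,
                            resolve_overlaps = TRUE) {
  if (length(signal) == 0) stop("empty signal")
  stopifnot(max_cost >= 0, min_match_duration > 0,
            max_match_duration >= min_match_duration, max_local_run >= 1,
            end_tolerance >= 0)
  rate <- template$sampling_rate
  t_sc <- template$samples / template$scaling
  x_sc <- as.numeric(signal) / template$scaling
  fin <- if (is.finite(max_local_run)) {
    subseq_dtw_constrained_cpp(t_sc, x_sc, as.integer(max_local_run))
  } else {
    subseq_dtw_cpp(t_sc, x_sc)
  }
  cand <- dtw_candidates(fin$cost, fin$start, max_cost, end_tolerance)
  if (nrow(cand) > 0) {
    dur <- (cand$end - cand$start) / rate
    cand <- cand[dur >= min_match_duration & dur <= max_match_duration, ]
  }
  if (resolve_overlaps && nrow(cand) > 1) {
    cand <- resolve_overlapping_matches(cand)
  }
  cand <- cand[order(cand$start), ]
  tibble::tibble(
    stride_id = seq_len(nrow(cand)) - 1L,
    start = as.integer(cand$start), end = as.integer(cand$end),
    cost = cand$cost
  )
}

# Candidate ends: one candidate per cost valley of the final row, at the
# RIGHT edge of the valley's bottom plateau. The plateau is tracked with a
# hysteresis `tol`: while the cost stays within `tol` of the running valley
# minimum the candidate end keeps extending; once it rises above
# `min + tol` the candidate is emitted and a new valley starts. On exactly
# flat stance the plateau is exact (tol plays no role) and the end lands on
# the last sample before the next swing onset; under sensor noise the
# plateau drifts upward by the accumulated squared noise, which `tol`
# absorbs without letting the end creep into the next swing (whose
# per-sample cost increments are orders of magnitude larger).
dtw_candidates <- function(cost, start, max_cost, tol) {
  n <- length(cost)
  out_end <- integer(); out_start <- integer(); out_cost <- numeric()
  min_val <- Inf; min_j <- 0L; ext_j <- 0L
  emit <- function() {
    if (is.finite(min_val) && min_val <= max_cost && start[min_j] > 0) {
      out_end <<- c(out_end, ext_j)
      out_start <<- c(out_start, start[ext_j] - 1L)
      out_cost <<- c(out_cost, cost[ext_j])
    }
  }
  for (j in seq_len(n)) {
    cj <- cost[j]
    if (!is.finite(cj)) next
    if (cj < min_val) {
      min_val <- cj; min_j <- j; ext_j <- j
    } else if (cj <= min_val + tol) {
      ext_j <- j
    } else {
      emit()
      min_val <- cj; min_j <- j; ext_j <- j
    }
  }
  emit()
  tibble::tibble(start = out_start, end = out_end, cost = out_cost)
}

# keep lower-cost match among overlapping candidates (ties: earlier start)
resolve_overlapping_matches <- function(cand) {
  cand <- cand[order(cand$cost, cand$start), ]
  kept <- logical(0)
  ks <- integer(0); ke <- integer(0)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (all(e <= ks | s >= ke)) {
      take[i] <- TRUE
      ks <- c(ks, s); ke <- c(ke, e)
    }
  }
  cand[take, ]
}

#' Snap stride borders to local signal minima
#'
#' Moves every stride border to the argmin of `signal` within a window of
#' `snap_window` seconds centered on its current position. Moves that would
#' break the stride-list invariants (sorted, non-overlapping, start < end)
#' are reverted pairwise.
#'
#' @param strides a stride list tibble.
#' @param signal the 1-D signal the strides live on.
#' @param snap_window full window width in seconds (0 leaves borders
#'   untouched).
#' @param rate sampling rate in Hz.
#' @return the adjusted stride list.
#' @export
snap_to_min <- function(strides, signal, snap_window = 0.1, rate) {
  stopifnot(snap_window >= 0)
  if (snap_window == 0 || nrow(strides) == 0) return(strides)
  half <- as.integer(floor(snap_window * rate / 2))
  if (half < 1) return(strides)
  n <- length(signal)
  snap1 <- function(b) {
    lo <- max(0L, as.integer(b) - half); hi <- min(n - 1L, as.integer(b) + half)
    if (lo >= hi) return(as.integer(b))
    win <- signal[(lo + 1):(hi + 1)]
    as.integer(lo + which.min(win) - 1L)
  }
  new_start <- vapply(strides$start, snap1, 0L)
  new_end <- vapply(strides$end, snap1, 0L)
  out <- strides
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  # revert violating moves: start < end within a stride, no overlap between
  # consecutive strides
  bad <- out$start >= out$end
  if (nrow(out) > 1) {
    ov <- c(out$start[-1] < out$end[-nrow(out)], FALSE)
    bad <- bad | ov | c(FALSE, ov[-nrow(out)])
  }
  out$start[bad] <- strides$start[bad]
  out$end[bad] <- strides$end[bad]
  validate_interval_list(out)
  out
}
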