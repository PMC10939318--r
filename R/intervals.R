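#' Interval, stride and event lists
#'
#' All interval-like objects in stridewise are tibbles of 0-based,
#' half-open `[start, end)` sample-index intervals, sorted by `start` and
#' non-overlapping:
#'
#' * an *interval list* has columns `start`, `end` (e.g. ZUPT regions),
#' * a *stride list* additionally has a `stride_id` column,
#' * an *event list* has `stride_id`, `start`, `end`, `tc`, `ic`,
#'   `min_vel`, `detectable`; the event columns are absolute sample
#'   indices (NA when not detectable).
#'
#' @param start,end integer vectors of 0-based sample indices.
#' @param stride_id optional integer ids; defaults to `seq_along(start) - 1`.
#' @return a validated tibble.
#' @name interval_lists
NULL

#' @rdname interval_lists
#' @export
interval_list <- function(start = integer(), end = integer()) {
  out <- tibble::tibble(start = as.integer(start), end = as.integer(end))
  validate_interval_list(out)
}

#' @rdname interval_lists
#' @export
stride_list <- function(start = integer(), end = integer(),
                        stride_id = NULL) {
  if (is.null(stride_id)) stride_id <- seq_along(start) - 1L
  out <- tibble::tibble(
    stride_id = as.integer(stride_id),
    start = as.integer(start), end = as.integer(end)
  )
  validate_interval_list(out)
}

#' @rdname interval_lists
#' @param x an interval-list-like data frame.
#' @export
validate_interval_list <- function(x) {
  stopifnot(all(c("start", "end") %in% names(x)))
  if (nrow(x) == 0) return(tibble::as_tibble(x))
  if (any(x$start < 0)) stop("interval starts must be >= 0")
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end")
  if (is.unsorted(x$start, strictly = TRUE) && nrow(x) > 1) {
    stop("intervals must be sorted by start")
  }
  if (nrow(x) > 1 && any(x$start[-1] < x$end[-nrow(x)])) {
    stop("intervals must be non-overlapping")
  }
  tibble::as_tibble(x)
}

# merge touching or overlapping intervals into maximal regions (idempotent)
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(interval_list())
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  interval_list(c(out_s, ms), c(out_e, me))
}

#' Read and write interval lists as JSON
#'
#' Serialized files carry the index convention string
#' `"0-based,half-open"` so files are self-describing.
#'
#' @param x interval or stride list tibble.
#' @param path file path.
#' @return `read_interval_json()` returns the tibble; writers return the
#'   path invisibly.
#' @export
write_interval_json <- function(x, path) {
  payload <- list(
    convention = "0-based,half-open",
    intervals = as.data.frame(x)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_interval_json
#' @export
read_interval_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$convention, "0-based,half-open")) {
    stop("unsupported index convention: ", payload$convention)
  }
  x <- tibble::as_tibble(payload$intervals)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_interval_list(x)
}

#' @rdname interval_lists
#' @param tc,ic,min_vel absolute event sample indices (NA allowed when
#'   `detectable` is FALSE).
#' @param detectable logical flag per stride.
#' @export
event_list <- function(stride_id, start, end, tc, ic, min_vel,
                       detectable = TRUE) {
  out <- tibble::tibble(
    stride_id = as.integer(stride_id),
    start = as.integer(start), end = as.integer(end),
    tc = as.integer(tc), ic = as.integer(ic),
    min_vel = as.integer(min_vel),
    detectable = rep_len(as.logical(detectable), length(stride_id))
  )
  validate_event_list(out)
}

#' @rdname interval_lists
#' @export
validate_event_list <- function(x) {
  validate_interval_list(x)
  ok <- x$detectable
  within <- function(e) is.na(e) | (e >= x$start & e < x$end)
  if (any(ok & !(within(x$tc) & within(x$ic) & within(x$min_vel)))) {
    stop("event indices must lie within their stride interval")
  }
  if (any(ok & !is.na(x$tc) & !is.na(x$ic) & x$tc >= x$ic)) {
    stop("terminal contact must precede initial contact within a stride")
  }
  tibble::as_tibble(x)
}
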