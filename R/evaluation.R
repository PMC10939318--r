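#' Match detected against reference stride lists
#'
#' A detected stride is matchable to a reference stride iff both its start
#' and its end lie within `tolerance` seconds of the reference borders
#' (tolerance converted to samples by rounding half up). Among all feasible
#' pairings a maximum-cardinality one-to-one matching is returned; ties
#' between equally large matchings are broken by the smaller total summed
#' border distance, then by preferring earlier reference strides.
#'
#' @param detected,reference stride list tibbles at the same sampling rate.
#' @param tolerance matching tolerance in seconds (default 30 ms).
#' @param rate sampling rate in Hz.
#' @return an object of class `stride_matching`: a list with `pairs`
#'   (tibble `detected_id`, `reference_id`, `distance`), `false_positives`
#'   (unmatched detected ids), `false_negatives` (unmatched reference ids)
#'   and `tolerance`.
#' @export
match_stride_lists <- function(detected, reference, tolerance = 0.03,
                               rate) {
  if (tolerance < 0) stop("tolerance must be non-negative")
  tol <- floor(tolerance * rate + 0.5)  # samples, rounded half up
  nd <- nrow(detected); nr <- nrow(reference)
  feasible <- list()
  for (i in seq_len(nd)) {
    ds <- abs(reference$start - detected$start[i])
    de <- abs(reference$end - detected$end[i])
    j <- which(ds <= tol & de <= tol)
    feasible[[i]] <- if (length(j)) cbind(ref = j, dist = ds[j] + de[j]) else
      cbind(ref = integer(), dist = integer())
  }
  m <- mcmf_assignment(feasible, nd, nr)
  pairs <- tibble::tibble(
    detected_id = detected$stride_id[m$det],
    reference_id = reference$stride_id[m$ref],
    distance = m$dist
  )
  structure(list(
    pairs = pairs,
    false_positives = detected$stride_id[setdiff(seq_len(nd), m$det)],
    false_negatives = reference$stride_id[setdiff(seq_len(nr), m$ref)],
    tolerance = tolerance
  ), class = "stride_matching")
}

#' @export
print.stride_matching <- function(x, ...) {
  cat(sprintf("# stride matching: %d TP, %d FP, %d FN (tolerance %g s)\n",
              nrow(x$pairs), length(x$false_positives),
              length(x$false_negatives), x$tolerance))
  invisible(x)
}

# Min-cost maximum-cardinality assignment by successive shortest
# augmenting paths (Bellman-Ford on the residual graph). Edge cost is
# lexicographic (border distance, reference index), scalarized as
# dist * (nr^2 + 1) + ref_index, which is exact because distances are
# integers.
mcmf_assignment <- function(feasible, nd, nr) {
  match_of_det <- rep(NA_integer_, nd)   # ref index matched to detected i
  match_of_ref <- rep(NA_integer_, nr)
  scale <- nr^2 + 1
  cost <- function(i, j) {
    f <- feasible[[i]]
    f[f[, "ref"] == j, "dist"] * scale + j
  }
  repeat {
    # Bellman-Ford over nodes: detected 1..nd, refs nd+1..nd+nr
    INF <- Inf
    distd <- rep(INF, nd); distr <- rep(INF, nr)
    prevr <- rep(NA_integer_, nr)        # detected node that reached ref j
    distd[is.na(match_of_det)] <- 0
    repeat {
      improved <- FALSE
      for (i in seq_len(nd)) {
        if (!is.finite(distd[i])) next
        f <- feasible[[i]]
        for (r in seq_len(nrow(f))) {
          j <- f[r, "ref"]
          if (identical(match_of_det[i], j)) next  # forward edges only
          nc <- distd[i] + f[r, "dist"] * scale + j
          if (nc < distr[j] - 1e-9) {
            distr[j] <- nc; prevr[j] <- i; improved <- TRUE
            # residual backward edge: ref j -> its current detected match
            i2 <- match_of_ref[j]
            if (!is.na(i2)) {
              bc <- distr[j] - cost(i2, j)
              if (bc < distd[i2] - 1e-9) distd[i2] <- bc
            }
          }
        }
      }
      # propagate backward edges found after forward scan
      for (j in seq_len(nr)) {
        i2 <- match_of_ref[j]
        if (!is.na(i2) && is.finite(distr[j])) {
          bc <- distr[j] - cost(i2, j)
          if (bc < distd[i2] - 1e-9) { distd[i2] <- bc; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    free_refs <- which(is.na(match_of_ref) & is.finite(distr))
    if (length(free_refs) == 0) break
    j <- free_refs[which.min(distr[free_refs])]
    # augment along the path ending at free ref j
    repeat {
      i <- prevr[j]
      jprev <- match_of_det[i]            # ref i was matched to (NA if free)
      match_of_det[i] <- j
      match_of_ref[j] <- i
      if (is.na(jprev)) break
      j <- jprev
    }
  }
  det <- which(!is.na(match_of_det))
  ref <- match_of_det[det]
  dist <- vapply(seq_along(det), function(k) {
    f <- feasible[[det[k]]]
    as.numeric(f[f[, "ref"] == ref[k], "dist"])
  }, 0)
  list(det = det, ref = ref, dist = dist)
}

#' Precision, recall and F1 from a stride matching
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, `f1` is their
#' harmonic mean (`2 TP / (2 TP + FP + FN)`). Scores with an empty
#' denominator are `NA` (undefined), never silently 0.
#'
#' @param m a `stride_matching` (or a list with `tp`, `fp`, `fn` counts).
#' @return a one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
precision_recall_f1 <- function(m) {
  if (inherits(m, "stride_matching")) {
    tp <- nrow(m$pairs)
    fp <- length(m$false_positives)
    fn <- length(m$false_negatives)
  } else {
    tp <- m$tp; fp <- m$fp; fn <- m$fn
  }
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn)
  )
}

#' Per-stride parameter errors with per-test and per-fold aggregation
#'
#' Computes per-stride signed and absolute errors between predicted and
#' reference gait parameters (strides aligned beforehand, e.g. by
#' [match_stride_lists()]; unmatched strides are excluded and counted).
#' Aggregates at two levels that mirror the dual reporting of benchmark
#' results: *per test* (mean/median over strides within one recording) and
#' *per fold* (mean/median of the per-test values within a cross-validation
#' fold). The two aggregation schemes generally yield different numbers and
#' must not be compared across schemes.
#'
#' @param pred,ref tibbles with a shared id column `stride` plus the value
#'   column and optional `test` / `fold` columns.
#' @param value name of the parameter column to compare.
#' @param stride,test,fold column names for stride id, recording id and CV
#'   fold id (`test`/`fold` optional).
#' @return an object of class `parameter_errors`: list of tibbles
#'   `per_stride`, `per_test`, `per_fold` plus `n_unmatched`.
#' @export
parameter_errors <- function(pred, ref, value, stride = "stride_id",
                             test = NULL, fold = NULL) {
  keys <- c(stride, test, fold)
  joined <- dplyr::inner_join(
    dplyr::rename(pred[, c(keys, value)], pred = dplyr::all_of(value)),
    dplyr::rename(ref[, c(keys, value)], ref = dplyr::all_of(value)),
    by = keys
  )
  if (nrow(joined) == 0) stop("no overlapping strides between pred and ref")
  n_unmatched <- (nrow(pred) - nrow(joined)) + (nrow(ref) - nrow(joined))
  per_stride <- dplyr::mutate(joined,
    error = .data$pred - .data$ref,
    abs_error = abs(.data$pred - .data$ref))
  agg <- function(d, by) {
    dplyr::summarise(dplyr::group_by(d, dplyr::across(dplyr::all_of(by))),
      mean_error = mean(.data$error),
      mae = mean(.data$abs_error),
      median_ae = stats::median(.data$abs_error),
      n = dplyr::n(), .groups = "drop")
  }
  per_test <- if (!is.null(test)) agg(per_stride, c(fold, test)) else NULL
  per_fold <- if (!is.null(test) && !is.null(fold)) {
    dplyr::summarise(dplyr::group_by(per_test, dplyr::across(dplyr::all_of(fold))),
      mean_error = mean(.data$mean_error),
      mae = mean(.data$mae),
      median_ae = stats::median(.data$mae),
      n_tests = dplyr::n(), .groups = "drop")
  } else NULL
  structure(list(per_stride = per_stride, per_test = per_test,
                 per_fold = per_fold, n_unmatched = n_unmatched),
            class = "parameter_errors")
}

#' Grouped k-fold cross-validation
#'
#' Splits dataset items into k folds such that no group (e.g. participant)
#' appears in more than one test fold. Fold assignment is deterministic
#' given `seed`: group labels are sorted, shuffled with the seed and dealt
#' round-robin. For each fold an optional `fit` function receives the
#' training items and returns tuned parameters, which are passed to
#' `score` for every test item.
#'
#' @param data a tibble with one row per dataset item.
#' @param group name of the group-label column.
#' @param k number of folds (must not exceed the number of groups).
#' @param score `function(item, params)` returning a named list / one-row
#'   data frame of scores for one test item (a one-row tibble).
#' @param fit optional `function(train_data)` returning tuned parameters
#'   (default `NULL`: the pipeline has no tunable parameters).
#' @param seed integer seed for the fold shuffle.
#' @return an object of class `cv_result`: list with `folds` (tibble
#'   `group`, `fold`), `results` (per-item scores with fold ids) and
#'   `summary` (per-fold means of numeric scores).
#' @export
grouped_cross_validation <- function(data, group, k, score, fit = NULL,
                                     seed = 1) {
  groups <- sort(unique(data[[group]]))
  if (k > length(groups)) {
    stop("k = ", k, " exceeds the number of groups (", length(groups), ")")
  }
  shuffled <- withr::with_seed(seed, sample(groups))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  folds <- tibble::tibble(group = shuffled, fold = unname(fold_of))
  results <- purrr::map(seq_len(k), function(f) {
    test_groups <- folds$group[folds$fold == f]
    test_idx <- data[[group]] %in% test_groups
    params <- if (!is.null(fit)) fit(data[!test_idx, , drop = FALSE]) else NULL
    purrr::map(which(test_idx), function(i) {
      s <- score(data[i, , drop = FALSE], params)
      tibble::as_tibble(as.list(s)) |>
        dplyr::mutate(item = i, group = data[[group]][i], fold = f,
                      .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  num_cols <- names(results)[vapply(results, is.numeric, TRUE)]
  num_cols <- setdiff(num_cols, c("item", "fold"))
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$fold),
    dplyr::across(dplyr::all_of(num_cols), mean), .groups = "drop")
  structure(list(folds = folds, results = results, summary = summary,
                 seed = seed),
            class = "cv_result")
}
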