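# Independent brute-force oracles used across the suite. These re-derive
# the same mathematical definitions with the most literal implementation
# possible (full matrices, explicit loops, explicit path backtracking) so
# that they share no code path with the package implementations.

# --- subsequence DTW: full-matrix DP with explicit backtracking ----------

# Accumulated-cost matrix for a scaled template/signal pair.
# Returns list(D = M x N cost matrix)
oracle_dtw_matrix <- function(tmpl, sig) {
  M <- length(tmpl); N <- length(sig)
  D <- matrix(Inf, M, N)
  for (j in 1:N) D[1, j] <- (tmpl[1] - sig[j])^2
  for (i in 2:M) {
    for (j in 1:N) {
      c_ij <- (tmpl[i] - sig[j])^2
      best <- Inf
      if (j > 1) best <- D[i - 1, j - 1]                 # diagonal
      if (D[i - 1, j] < best) best <- D[i - 1, j]        # vertical
      if (j > 1 && D[i, j - 1] < best) best <- D[i, j - 1]  # horizontal
      D[i, j] <- c_ij + best
    }
  }
  D
}

# Backtrack the best path from (M, j) to row 1; returns the start column.
# Tie preference: diagonal, then vertical, then horizontal.
oracle_dtw_start <- function(D, j) {
  i <- nrow(D)
  while (i > 1) {
    cands <- c(if (j > 1) D[i - 1, j - 1] else Inf,
               D[i - 1, j],
               if (j > 1) D[i, j - 1] else Inf)
    k <- which.min(cands)  # which.min takes the first minimum: diag>vert>horz
    if (k == 1) { i <- i - 1; j <- j - 1 }
    else if (k == 2) i <- i - 1
    else j <- j - 1
  }
  j
}

# Candidate selection: one candidate per cost valley, right edge of the
# tolerance plateau (mirrors the documented semantics, independent code).
oracle_dtw_candidates <- function(cost, starts, max_cost, tol) {
  out <- NULL
  min_val <- Inf; min_j <- 0L; ext_j <- 0L
  flush <- function(out) {
    if (is.finite(min_val) && min_val <= max_cost && starts[min_j] > 0) {
      rbind(out, c(start = starts[ext_j] - 1L, end = ext_j,
                   cost = cost[ext_j]))
    } else out
  }
  for (j in seq_along(cost)) {
    if (!is.finite(cost[j])) next
    if (cost[j] < min_val) {
      min_val <- cost[j]; min_j <- j; ext_j <- j
    } else if (cost[j] <= min_val + tol) {
      ext_j <- j
    } else {
      out <- flush(out)
      min_val <- cost[j]; min_j <- j; ext_j <- j
    }
  }
  out <- flush(out)
  out
}

# Full oracle for the plain algorithm: returns a data.frame of matches
# (start, end 0-based half-open, cost) after duration filtering and
# lower-cost-first overlap resolution.
oracle_subsequence_dtw <- function(signal, template, max_cost,
                                   min_dur, max_dur, rate,
                                   scaling = 1, tol = 1e-4,
                                   resolve = TRUE) {
  t_sc <- template / scaling
  x_sc <- signal / scaling
  D <- oracle_dtw_matrix(t_sc, x_sc)
  fin <- D[nrow(D), ]
  starts <- vapply(seq_along(fin), function(j) oracle_dtw_start(D, j), 0)
  cand <- oracle_dtw_candidates(fin, starts, max_cost, tol)
  if (is.null(cand)) {
    return(data.frame(start = integer(), end = integer(), cost = numeric()))
  }
  cand <- as.data.frame(cand)
  dur <- (cand$end - cand$start) / rate
  cand <- cand[dur >= min_dur & dur <= max_dur, , drop = FALSE]
  if (resolve && nrow(cand) > 1) {
    cand <- cand[order(cand$cost, cand$start), , drop = FALSE]
    keep <- rep(FALSE, nrow(cand))
    ks <- integer(); ke <- integer()
    for (i in seq_len(nrow(cand))) {
      if (all(cand$end[i] <= ks | cand$start[i] >= ke)) {
        keep[i] <- TRUE
        ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# --- constrained subsequence DTW oracle ----------------------------------
# Full 3-D DP over states (i, j, s): s = 1 "arrived by diagonal/free
# start", s = 2..R+1 vertical run 1..R, s = R+2..2R+1 horizontal run 1..R.
# Parent pointers allow literal backtracking to the start column.
oracle_subsequence_dtw_constrained <- function(signal, template, max_run,
                                               max_cost, min_dur, max_dur,
                                               rate, scaling = 1,
                                               tol = 1e-4) {
  t_sc <- template / scaling
  x_sc <- signal / scaling
  M <- length(t_sc); N <- length(x_sc); R <- max_run; S <- 2 * R + 1
  D <- array(Inf, c(M, N, S))
  # parent encoding: 0 = none (free start), otherwise c(i, j, s)
  P <- array(0L, c(M, N, S, 3))
  for (j in 1:N) D[1, j, 1] <- (t_sc[1] - x_sc[j])^2
  for (j in 1:N) {
    for (i in 1:M) {
      if (i == 1) next
      c_ij <- (t_sc[i] - x_sc[j])^2
      # diagonal from any state at (i-1, j-1)
      if (j > 1) {
        best <- Inf; bs <- 0L
        for (s in 1:S) if (D[i - 1, j - 1, s] < best) { best <- D[i - 1, j - 1, s]; bs <- s }
        if (is.finite(best)) {
          D[i, j, 1] <- c_ij + best
          P[i, j, 1, ] <- c(i - 1L, j - 1L, bs)
        }
      }
      # vertical from (i-1, j): fresh run from diag or any horizontal state
      best <- D[i - 1, j, 1]; bs <- 1L
      if (R >= 1) for (r in 1:R) {
        if (D[i - 1, j, R + 1 + r] < best) { best <- D[i - 1, j, R + 1 + r]; bs <- R + 1L + r }
      }
      if (is.finite(best)) {
        D[i, j, 2] <- c_ij + best
        P[i, j, 2, ] <- c(i - 1L, j, bs)
      }
      if (R >= 2) for (r in 1:(R - 1)) {
        if (is.finite(D[i - 1, j, 1 + r])) {
          D[i, j, 2 + r] <- c_ij + D[i - 1, j, 1 + r]
          P[i, j, 2 + r, ] <- c(i - 1L, j, 1L + r)
        }
      }
      # horizontal from (i, j-1): fresh run from diag or any vertical state
      if (j > 1) {
        best <- D[i, j - 1, 1]; bs <- 1L
        for (r in 1:R) {
          if (D[i, j - 1, 1 + r] < best) { best <- D[i, j - 1, 1 + r]; bs <- 1L + r }
        }
        if (is.finite(best)) {
          D[i, j, R + 2] <- c_ij + best
          P[i, j, R + 2, ] <- c(i, j - 1L, bs)
        }
        if (R >= 2) for (r in 1:(R - 1)) {
          if (is.finite(D[i, j - 1, R + 1 + r])) {
            D[i, j, R + 2 + r] <- c_ij + D[i, j - 1, R + 1 + r]
            P[i, j, R + 2 + r, ] <- c(i, j - 1L, R + 1L + r)
          }
        }
      }
    }
  }
  fin <- numeric(N); fstate <- integer(N)
  for (j in 1:N) {
    best <- Inf; bs <- 0L
    for (s in 1:S) if (D[M, j, s] < best) { best <- D[M, j, s]; bs <- s }
    fin[j] <- best; fstate[j] <- bs
  }
  starts <- integer(N)
  for (j in 1:N) {
    if (!is.finite(fin[j])) { starts[j] <- -1L; next }
    cur <- c(M, j, fstate[j])
    repeat {
      par <- P[cur[1], cur[2], cur[3], ]
      if (all(par == 0L)) break
      cur <- par
    }
    starts[j] <- cur[2]
  }
  cand <- oracle_dtw_candidates(fin, starts, max_cost, tol)
  if (is.null(cand)) {
    return(data.frame(start = integer(), end = integer(), cost = numeric()))
  }
  cand <- as.data.frame(cand)
  dur <- (cand$end - cand$start) / rate
  cand <- cand[dur >= min_dur & dur <= max_dur, , drop = FALSE]
  if (nrow(cand) > 1) {
    cand <- cand[order(cand$cost, cand$start), , drop = FALSE]
    keep <- rep(FALSE, nrow(cand))
    ks <- integer(); ke <- integer()
    for (i in seq_len(nrow(cand))) {
      if (all(cand$end[i] <= ks | cand$start[i] >= ke)) {
        keep[i] <- TRUE
        ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[order(cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# --- exhaustive optimal assignment for stride matching -------------------
# Enumerates every one-to-one pairing of feasible (detected, reference)
# pairs and returns the best by (cardinality desc, total distance asc,
# total reference-index asc). Only viable for small instances.
oracle_match <- function(detected, reference, tol_samples) {
  nd <- nrow(detected); nr <- nrow(reference)
  feas <- list()
  for (i in seq_len(nd)) {
    js <- which(abs(reference$start - detected$start[i]) <= tol_samples &
                  abs(reference$end - detected$end[i]) <= tol_samples)
    feas[[i]] <- js
  }
  best <- list(card = -1, dist = Inf, refsum = Inf, pairs = NULL)
  assign_rec <- function(i, used, pairs, dist) {
    if (i > nd) {
      card <- nrow(pairs) %||% 0
      refsum <- if (card > 0) sum(pairs[, 2]) else 0
      better <- card > best$card ||
        (card == best$card && dist < best$dist - 1e-12) ||
        (card == best$card && abs(dist - best$dist) <= 1e-12 &&
           refsum < best$refsum)
      if (better) best <<- list(card = card, dist = dist, refsum = refsum,
                                pairs = pairs)
      return(invisible())
    }
    # skip detected i
    assign_rec(i + 1, used, pairs, dist)
    for (j in feas[[i]]) {
      if (!(j %in% used)) {
        d <- abs(reference$start[j] - detected$start[i]) +
          abs(reference$end[j] - detected$end[i])
        assign_rec(i + 1, c(used, j), rbind(pairs, c(i, j)), dist + d)
      }
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  assign_rec(1, integer(), NULL, 0)
  best
}

# --- sliding-window static-region oracle ---------------------------------
# Evaluates every window placement literally and unions passing windows.
oracle_static_regions <- function(stat_fun, n, w, starts, threshold) {
  mask <- rep(FALSE, n)
  for (s in starts) {
    if (stat_fun(s) < threshold) mask[(s + 1):(s + w)] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  idx <- which(r$values)
  data.frame(start = ends[idx] - r$lengths[idx], end = ends[idx])
}

# quick helper: jaccard overlap of two [start,end) intervals
jaccard_interval <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  union <- (a2 - a1) + (b2 - b1) - inter
  inter / union
}
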