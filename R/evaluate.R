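# Ground-truth comparison utilities for simulation studies: event matching
# and per-cycle timing errors against a simulated walk's truth table.

#' Match detected events to ground-truth strikes
#'
#' Greedy one-to-one nearest matching between detected event times and true
#' strike times within a tolerance, yielding detection recall and precision.
#'
#' @param detected numeric vector of detected event times (seconds).
#' @param truth numeric vector of true strike times.
#' @param tol matching tolerance in seconds (default 0.25, about half a
#'   typical step time).
#' @return list: `pairs` (data.frame `detected`, `truth`), `recall`,
#'   `precision`, `n_detected`, `n_truth`.
#' @export
match_events <- function(detected, truth, tol = 0.25) {
  used_d <- rep(FALSE, length(detected))
  used_t <- rep(FALSE, length(truth))
  pairs <- data.frame(detected = numeric(), truth = numeric())
  if (length(detected) && length(truth)) {
    dmat <- abs(outer(detected, truth, "-"))
    repeat {
      i <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      if (dmat[i[1], i[2]] > tol) break
      pairs <- rbind(pairs, data.frame(detected = detected[i[1]],
                                       truth = truth[i[2]]))
      used_d[i[1]] <- used_t[i[2]] <- TRUE
      dmat[i[1], ] <- Inf
      dmat[, i[2]] <- Inf
      if (all(used_d) || all(used_t)) break
    }
  }
  list(pairs = pairs,
       recall = if (length(truth)) sum(used_t) / length(truth) else NA_real_,
       precision = if (length(detected)) sum(used_d) / length(detected)
                   else NA_real_,
       n_detected = length(detected), n_truth = length(truth))
}

#' Per-cycle timing errors against a simulated walk's ground truth
#'
#' Matches estimated cycles to true footsteps by strike time, derives the
#' duration parameters from both event sets with
#' [compute_temporal_params()], and returns the matched per-cycle errors.
#'
#' @param cycles estimated cycles (data.frame with `t_strike`, `t_off`), e.g.
#'   from [estimate_temporal()].
#' @param truth a `gait_truth` data.frame from [generate_walk()].
#' @param tol strike matching tolerance in seconds.
#' @return data.frame of matched-cycle errors (estimate minus truth):
#'   `strike`, `off`, `step_time`, `stride_time`, `stance_time`,
#'   `swing_time`, `double_support1`, `double_support2`, `single_support`.
#' @export
timing_errors <- function(cycles, truth, tol = 0.3) {
  m <- match_events(cycles$t_strike, truth$t_strike, tol = tol)
  if (nrow(m$pairs) < 2) {
    return(data.frame(strike = numeric(), off = numeric(),
                      step_time = numeric(), stride_time = numeric(),
                      stance_time = numeric(), swing_time = numeric(),
                      double_support1 = numeric(),
                      double_support2 = numeric(),
                      single_support = numeric()))
  }
  ei <- match(m$pairs$detected, cycles$t_strike)
  ti <- match(m$pairs$truth, truth$t_strike)
  ord <- order(ti)
  ei <- ei[ord]; ti <- ti[ord]
  est <- compute_temporal_params(cycles)
  tru <- compute_temporal_params(
    data.frame(t_strike = truth$t_strike, t_off = truth$t_off,
               side = truth$side))
  # duration errors are only meaningful where the matched cycles are
  # consecutive in both sequences (ahead for step/stride, behind for the
  # parameters that reference the previous cycle's foot-off)
  k <- length(ei)
  consec2 <- c(diff(ei) == 1 & diff(ti) == 1, FALSE)       # i, i+1 matched
  consec3 <- c(consec2[-1] & consec2[-k], FALSE)           # i .. i+2 matched
  prev_ok <- c(FALSE, consec2[-k])                         # i-1, i matched
  out <- data.frame(
    strike = est$t_strike[ei] - tru$t_strike[ti],
    off = est$t_off[ei] - tru$t_off[ti],
    step_time = est$step_time[ei] - tru$step_time[ti],
    stride_time = est$stride_time[ei] - tru$stride_time[ti],
    stance_time = est$stance_time[ei] - tru$stance_time[ti],
    swing_time = est$swing_time[ei] - tru$swing_time[ti],
    double_support1 = est$double_support1[ei] - tru$double_support1[ti],
    double_support2 = est$double_support2[ei] - tru$double_support2[ti],
    single_support = est$single_support[ei] - tru$single_support[ti]
  )
  out$step_time[!consec2] <- NA
  out$double_support2[!consec2] <- NA
  out$stride_time[!consec3] <- NA
  out$swing_time[!consec3] <- NA
  out$double_support1[!prev_ok] <- NA
  out$single_support[!(prev_ok & consec2)] <- NA
  out
}

#' Root-mean-square error ignoring NA
#' @param x numeric vector of errors.
#' @return RMSE, or `NA` for an all-`NA` input.
#' @export
rmse <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean(x^2))
}
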