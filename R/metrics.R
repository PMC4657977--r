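## Behavioural statistics from trajectories -----------------------------------
##
## Everything here is computed from the recorded head/centroid/tail
## kinematics alone, never from the engine's internal state, mirroring how
## tracked larvae are analysed.

#' Bearing relative to the local odour gradient
#'
#' Signed angle between the body axis and the local up-gradient direction,
#' wrapped to (-180, 180]. Zero means the body is aligned with the direction
#' of maximal concentration increase; positive bearing means the up-gradient
#' direction lies to the larva's left.
#'
#' @param alpha body angle, deg anticlockwise from +x.
#' @param grad_dir local up-gradient direction, deg (see
#'   [gradient_direction()]); `NA` where the gradient vanishes.
#' @return bearing in (-180, 180] deg; `NA` where the gradient is undefined.
#' @export
bearing <- function(alpha, grad_dir) {
  wrap_angle(grad_dir - alpha)
}

# Unwrap a degree series using shortest-arc increments, so a jump from 170
# to -170 counts as +20, not -340.
unwrap_deg <- function(a) {
  if (length(a) < 2) return(a)
  a[1] + c(0, cumsum(wrap_angle(diff(a))))
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  out <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  # shrink the window at the edges instead of dropping to NA
  half <- (k - 1) %/% 2
  for (i in seq_len(half)) {
    out[i] <- mean(x[seq_len(i + half)])
    out[n - i + 1] <- mean(x[seq(n - i + 1 - half, n)])
  }
  out
}

#' Body reorientation speed
#'
#' Central-difference derivative of the unwrapped body angle, smoothed with a
#' short moving average (tracked angles are noisy at the sample level; the
#' smoothing window is configurable).
#'
#' @param traj a `larva_trajectory` (or any data.frame with `t_s` and
#'   `alpha_deg`).
#' @param smooth smoothing window in seconds (default 0.3 s, i.e. 3 samples
#'   at the native recording rate; 0 disables). Expressed in time so that
#'   detection behaves the same across recording strides.
#' @return numeric vector of dalpha/dt in deg/s, one value per sample.
#' @export
reorientation_speed <- function(traj, smooth = 0.3) {
  t <- traj$t_s
  n <- length(t)
  if (n < 3) return(rep(0, n))
  au <- unwrap_deg(traj$alpha_deg)
  d <- numeric(n)
  d[2:(n - 1)] <- (au[3:n] - au[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (au[2] - au[1]) / (t[2] - t[1])
  d[n] <- (au[n] - au[n - 1]) / (t[n] - t[n - 1])
  dt_s <- median(diff(t))
  k <- max(1, round(smooth / dt_s))
  if (k %% 2 == 0) k <- k - 1
  moving_average(d, max(1, k))
}

# maximal TRUE runs of `above`, after closing gaps of <= hysteresis samples
threshold_intervals <- function(above, hysteresis = 1) {
  above[is.na(above)] <- FALSE
  if (hysteresis > 0 && length(above) > 2) {
    r <- rle(above)
    gap <- !r$values & r$lengths <= hysteresis
    # interior gaps only
    if (length(r$values) > 2) {
      interior <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
      r$values[gap & interior] <- TRUE
      above <- inverse.rle(r)
    }
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect turns in a trajectory
#'
#' A turn is a maximal period during which the magnitude of the body
#' reorientation speed exceeds `rate_threshold`; periods shorter than
#' `min_duration` are discarded. Turn direction is the sign of the net body
#' angle change over the period (shortest-arc convention), left = positive.
#' `delta_alpha` is measured from one sample before to one sample after the
#' above-threshold interval, so the full amplitude of a reorientation ramp
#' is captured (the finite-difference derivative is below threshold on the
#' boundary samples themselves).
#'
#' @param traj a `larva_trajectory`.
#' @param rate_threshold reorientation-speed threshold, deg/s.
#' @param min_duration minimum turn duration, s.
#' @param smooth smoothing window (s) for [reorientation_speed()].
#' @param hysteresis close below-threshold gaps of up to this duration (s);
#'   expressed in time so detection behaves consistently across strides.
#' @return data.frame of events: `kind`, `i_start`, `i_end` (row indices),
#'   `t_start`, `t_end`, `delta_alpha` (deg), `direction` ("left"/"right").
#' @export
detect_turns <- function(traj, rate_threshold = 12, min_duration = 1,
                         smooth = 0.3, hysteresis = 0.1) {
  n <- nrow(traj)
  empty <- data.frame(kind = character(), i_start = integer(), i_end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      delta_alpha = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (n < 3 || (traj$t_s[n] - traj$t_s[1]) < min_duration) return(empty)
  dadt <- reorientation_speed(traj, smooth)
  hyst_n <- floor(hysteresis / median(diff(traj$t_s)) + 1e-9)
  iv <- threshold_intervals(abs(dadt) > rate_threshold, hyst_n)
  if (nrow(iv) == 0) return(empty)
  au <- unwrap_deg(traj$alpha_deg)
  dur <- traj$t_s[iv[, "end"]] - traj$t_s[iv[, "start"]]
  keep <- dur >= min_duration
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0) return(empty)
  lo <- pmax(1L, iv[, "start"] - 1L)
  hi <- pmin(n, iv[, "end"] + 1L)
  da <- au[hi] - au[lo]
  data.frame(kind = "turn", i_start = iv[, "start"], i_end = iv[, "end"],
             t_start = traj$t_s[iv[, "start"]], t_end = traj$t_s[iv[, "end"]],
             delta_alpha = da,
             direction = ifelse(da > 0, "left", "right"),
             stringsAsFactors = FALSE)
}

#' Detect head casts in a trajectory
#'
#' A head cast is a maximal excursion of the head-body angle magnitude above
#' `threshold` (default 37 deg). Direction is the side of the peak angle.
#' One-sample dips below threshold are bridged (hysteresis) so discretisation
#' chatter does not split an excursion.
#'
#' @param traj a `larva_trajectory`.
#' @param threshold head-angle threshold, deg.
#' @param hysteresis gap-closing window, s (one native sample by default).
#' @return data.frame of events: `kind`, `i_start`, `i_end`, `t_start`,
#'   `t_end`, `amplitude` (peak `|theta|`, deg), `direction`.
#' @export
detect_head_casts <- function(traj, threshold = 37, hysteresis = 0.1) {
  hyst_n <- floor(hysteresis / median(diff(traj$t_s)) + 1e-9)
  iv <- threshold_intervals(abs(traj$theta_deg) > threshold, hyst_n)
  if (nrow(iv) == 0)
    return(data.frame(kind = character(), i_start = integer(), i_end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      amplitude = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  amp <- numeric(nrow(iv))
  dirn <- character(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    th <- traj$theta_deg[iv[i, "start"]:iv[i, "end"]]
    j <- which.max(abs(th))
    amp[i] <- abs(th[j])
    dirn[i] <- if (th[j] > 0) "left" else "right"
  }
  data.frame(kind = "head_cast", i_start = iv[, "start"], i_end = iv[, "end"],
             t_start = traj$t_s[iv[, "start"]], t_end = traj$t_s[iv[, "end"]],
             amplitude = amp, direction = dirn, stringsAsFactors = FALSE)
}

#' Classify events as to-high or to-low
#'
#' An event is "to high" if its direction of motion points towards the
#' up-gradient side at the event start: with positive bearing (gradient on
#' the larva's left) a left event is to-high, with negative bearing a right
#' event is to-high. Classification uses the direction of the movement, not
#' the final bearing, so a turn overshooting past alignment still counts as
#' to-high.
#'
#' @param events event data.frame from [detect_turns()] or
#'   [detect_head_casts()].
#' @param traj the trajectory the events came from.
#' @param field the `odour_field` (for the local gradient at the event-start
#'   centroid position).
#' @return `events` with added columns `bearing_start` (deg) and `class`
#'   ("to_high"/"to_low", `NA` where the gradient vanishes).
#' @export
classify_events <- function(events, traj, field) {
  if (nrow(events) == 0) {
    events$bearing_start <- numeric(0)
    events$class <- character(0)
    return(events)
  }
  p <- cbind(traj$mid_x_mm[events$i_start], traj$mid_y_mm[events$i_start])
  gd <- gradient_direction(field, p)
  beta <- bearing(traj$alpha_deg[events$i_start], gd)
  left <- events$direction == "left"
  cls <- ifelse(is.na(beta), NA_character_,
                ifelse((beta >= 0 & left) | (beta < 0 & !left),
                       "to_high", "to_low"))
  events$bearing_start <- beta
  events$class <- cls
  events
}

#' Associate head casts with the turn they precede
#'
#' A cast belongs to a turn if it starts within the 5 s preceding the turn's
#' initiation, or between the end of the previous turn and the initiation of
#' this turn, whichever interval is shorter.
#'
#' @param casts cast events ([detect_head_casts()]).
#' @param turns turn events ([detect_turns()]).
#' @param window association window, s.
#' @return `casts` with an added `turn_id` column (row index into `turns`,
#'   `NA` when unassociated).
#' @export
assign_casts_to_turns <- function(casts, turns, window = 5) {
  casts$turn_id <- rep(NA_integer_, nrow(casts))
  if (nrow(casts) == 0 || nrow(turns) == 0) return(casts)
  ord <- order(turns$t_start)
  for (j in ord) {
    w <- window
    prev <- turns$t_end[turns$t_end <= turns$t_start[j]]
    prev <- prev[prev < turns$t_start[j]]
    if (length(prev) > 0) w <- min(w, turns$t_start[j] - max(prev))
    sel <- is.na(casts$turn_id) &
      casts$t_start >= turns$t_start[j] - w &
      casts$t_start < turns$t_start[j]
    casts$turn_id[sel] <- j
  }
  casts
}

#' Straightness index of a path
#'
#' Straight-line distance between the first and last centroid positions
#' divided by the centroid path length: 1 for a perfectly direct path, 0 for
#' a closed loop.
#'
#' @param traj a `larva_trajectory`, or an n x 2 matrix of positions.
#' @return SI in \[0, 1\] (`NA` for a degenerate zero-length path).
#' @export
straightness_index <- function(traj) {
  p <- if (is.matrix(traj)) traj else cbind(traj$mid_x_mm, traj$mid_y_mm)
  if (nrow(p) < 2) return(NA_real_)
  steps <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  L <- sum(steps)
  if (L == 0) return(NA_real_)
  sqrt((p[nrow(p), 1] - p[1, 1])^2 + (p[nrow(p), 2] - p[1, 2])^2) / L
}

#' Preference index of a group of final positions
#'
#' `PI = (#side1 - #side2) / #total`. Larvae inside the centre-exclusion
#' band are excluded from the side counts but still count towards the total.
#' Positions are split into consecutive groups of `group_size` and one PI is
#' computed per group, plus the pooled PI over all positions.
#'
#' @param positions n x 2 matrix of final positions (see
#'   [final_positions()]), or a `larva_batch`.
#' @param partition a [choice_partition()].
#' @param group_size larvae per group (default 20).
#' @return list with `pooled` (single PI), `groups` (one PI per complete
#'   group) and the side counts.
#' @export
preference_index <- function(positions, partition = choice_partition(),
                             group_size = 20) {
  if (inherits(positions, "larva_batch")) positions <- final_positions(positions)
  stopifnot(inherits(partition, "choice_partition"))
  p <- as_points(positions)
  s <- drop(p %*% partition$u)
  side1 <- s > partition$half
  side2 <- s < -partition$half
  pi_of <- function(idx) (sum(side1[idx]) - sum(side2[idx])) / length(idx)
  n <- length(s)
  ngroups <- n %/% group_size
  groups <- if (ngroups > 0)
    vapply(seq_len(ngroups),
           function(g) pi_of(seq((g - 1) * group_size + 1, g * group_size)),
           numeric(1))
  else numeric(0)
  list(pooled = pi_of(seq_len(n)), groups = groups,
       n_side1 = sum(side1), n_side2 = sum(side2),
       n_excluded = sum(!side1 & !side2), n_total = n)
}

#' Chemotaxis index of a trajectory
#'
#' Fraction of recorded samples whose centroid lies inside the region of
#' interest.
#'
#' @param traj a `larva_trajectory`.
#' @param roi an `roi` object.
#' @return CI in \[0, 1\].
#' @export
chemotaxis_index <- function(traj, roi) {
  mean(in_roi(roi, cbind(traj$mid_x_mm, traj$mid_y_mm)))
}

#' First-head-cast direction relative to the gradient
#'
#' The fraction of run terminations whose first head cast sweeps towards the
#' side of higher concentration. The cast direction is read directly from
#' the recorded head-angle sweep immediately after each run-to-cast mode
#' change, and compared with the bearing sign at the moment of run
#' termination. This direct kinematic measure is not affected by the 1 s
#' turn-discard rule of [detect_turns()], which preferentially removes the
#' small, quickly-terminated (mostly to-high) turns and so dilutes the
#' event-pipeline version of this statistic (see [summary_statistics()]).
#'
#' @param trajs a `larva_batch`, a list of trajectories, or a single
#'   `larva_trajectory` (recorded at stride 1).
#' @param field the `odour_field`.
#' @return list with `fraction_to_high`, `n` (number of run terminations
#'   with a defined bearing and cast direction).
#' @export
first_cast_stats <- function(trajs, field) {
  if (inherits(trajs, "larva_batch")) trajs <- trajs$trajectories
  if (inherits(trajs, "larva_trajectory")) trajs <- list(trajs)
  tohigh <- logical(0)
  for (tr in trajs) {
    m <- tr$mode
    n <- length(m)
    if (n < 3) next
    k <- which(m[-n] == 0 & m[-1] == 1) # run -> head-cast transitions
    k <- k[k < n - 1]
    if (length(k) == 0) next
    beta <- bearing(tr$alpha_deg[k + 1],
                    gradient_direction(field,
                                       cbind(tr$mid_x_mm[k + 1], tr$mid_y_mm[k + 1])))
    sweep <- sign(tr$theta_deg[k + 2] - tr$theta_deg[k + 1])
    ok <- !is.na(beta) & sweep != 0 & beta != 0
    tohigh <- c(tohigh, (sign(beta[ok]) * sweep[ok]) > 0)
  }
  list(fraction_to_high = mean(tohigh), n = length(tohigh))
}

## Aggregate behavioural statistics -------------------------------------------

#' Behavioural statistics bundle for a batch of trajectories
#'
#' Computes the event-based summary used to compare model behaviour against
#' tracked larvae: turn-initiation rate and left-turn probability versus
#' bearing, reorientation speed during runs versus bearing, run-length and
#' pre/post-turn bearing distributions, head-casts-per-turn and cast-pattern
#' frequencies, the first-cast-to-high fraction, and (when a source point is
#' given) the mean distance-to-source time course with bootstrap confidence
#' bands.
#'
#' @param batch a `larva_batch` with full trajectories, or a list of
#'   `larva_trajectory` objects.
#' @param field the `odour_field` the larvae experienced.
#' @param source optional source position `c(x, y)` for the distance time
#'   course.
#' @param bin_width bearing bin width, deg.
#' @param nboot bootstrap resamples for the distance confidence band.
#' @param conf confidence level for the band.
#' @return a `larva_stats` list; see Details in the package vignette.
#' @export
summary_statistics <- function(batch, field, source = NULL, bin_width = 30,
                               nboot = 1000, conf = 0.95) {
  trajs <- if (inherits(batch, "larva_batch")) batch$trajectories else batch
  stopifnot(length(trajs) > 0)
  sbins <- seq(-180, 180, by = bin_width)
  abins <- seq(0, 180, by = bin_width)

  all_turns <- list()
  all_casts <- list()
  run_time_abs <- numeric(length(abins) - 1)
  run_reo_sum <- numeric(length(sbins) - 1)
  run_reo_n <- numeric(length(sbins) - 1)
  run_lengths <- numeric(0)
  per_turn_patterns <- character(0)
  casts_per_turn <- integer(0)
  first_classes <- character(0)

  for (tr in trajs) {
    dt_s <- median(diff(tr$t_s))
    turns <- classify_events(detect_turns(tr), tr, field)
    casts <- classify_events(detect_head_casts(tr), tr, field)
    casts <- assign_casts_to_turns(casts, turns)

    # bearing of every sample (subsample the gradient evaluation if large)
    gd <- gradient_direction(field, cbind(tr$mid_x_mm, tr$mid_y_mm))
    beta <- bearing(tr$alpha_deg, gd)

    # run samples = samples outside any reorientation burst (every interval
    # with |dalpha/dt| above threshold, regardless of duration, so that
    # realignment after sub-1s discarded turns does not count as running)
    in_turn <- rep(FALSE, nrow(tr))
    bursts <- threshold_intervals(abs(reorientation_speed(tr)) > 12, 1)
    if (nrow(bursts) > 0)
      for (j in seq_len(nrow(bursts)))
        in_turn[bursts[j, "start"]:bursts[j, "end"]] <- TRUE
    run_sel <- !in_turn & !is.na(beta)
    h <- graphics::hist(abs(beta[run_sel]), breaks = abins, plot = FALSE)
    run_time_abs <- run_time_abs + h$counts * dt_s
    dadt <- reorientation_speed(tr)
    bi <- cut(beta[run_sel], sbins, labels = FALSE, include.lowest = TRUE)
    ok <- !is.na(bi)
    run_reo_sum <- run_reo_sum + vapply(seq_len(length(sbins) - 1), function(b)
      sum(dadt[run_sel][ok & bi == b]), numeric(1))
    run_reo_n <- run_reo_n + tabulate(bi[ok], nbins = length(sbins) - 1)

    if (nrow(turns) > 1)
      run_lengths <- c(run_lengths, turns$t_start[-1] - turns$t_end[-nrow(turns)])
    if (nrow(turns) > 0) {
      for (j in seq_len(nrow(turns))) {
        cj <- casts[!is.na(casts$turn_id) & casts$turn_id == j, , drop = FALSE]
        cj <- cj[order(cj$t_start), , drop = FALSE]
        casts_per_turn <- c(casts_per_turn, nrow(cj))
        if (nrow(cj) > 0 && !anyNA(cj$class)) {
          per_turn_patterns <- c(per_turn_patterns,
                                 paste(ifelse(cj$class == "to_high", "H", "L"),
                                       collapse = ""))
          first_classes <- c(first_classes, cj$class[1])
        }
      }
    }
    all_turns[[length(all_turns) + 1]] <- turns
    all_casts[[length(all_casts) + 1]] <- casts
  }

  turns <- do.call(rbind, all_turns)
  casts <- do.call(rbind, all_casts)

  bearing_mid_abs <- (abins[-1] + abins[-length(abins)]) / 2
  bearing_mid <- (sbins[-1] + sbins[-length(sbins)]) / 2

  turn_counts_abs <- if (nrow(turns) > 0)
    graphics::hist(abs(turns$bearing_start[!is.na(turns$bearing_start)]),
                   breaks = abins, plot = FALSE)$counts
  else numeric(length(abins) - 1)

  left_prob <- rep(NA_real_, length(sbins) - 1)
  if (nrow(turns) > 0) {
    bi <- cut(turns$bearing_start, sbins, labels = FALSE, include.lowest = TRUE)
    for (b in seq_along(left_prob)) {
      sel <- !is.na(bi) & bi == b
      if (any(sel)) left_prob[b] <- mean(turns$direction[sel] == "left")
    }
  }

  dist_curve <- NULL
  if (!is.null(source)) {
    tmax <- min(vapply(trajs, function(tr) tr$t_s[nrow(tr)], numeric(1)))
    tgrid <- seq(0, floor(tmax), by = 1)
    D <- t(vapply(trajs, function(tr) {
      idx <- findInterval(tgrid, tr$t_s)
      sqrt((tr$mid_x_mm[idx] - source[1])^2 + (tr$mid_y_mm[idx] - source[2])^2)
    }, numeric(length(tgrid))))
    boots <- matrix(NA_real_, nboot, length(tgrid))
    for (b in seq_len(nboot))
      boots[b, ] <- colMeans(D[sample.int(nrow(D), replace = TRUE), , drop = FALSE])
    a <- (1 - conf) / 2
    dist_curve <- data.frame(t_s = tgrid, mean = colMeans(D),
                             lo = apply(boots, 2, quantile, probs = a),
                             hi = apply(boots, 2, quantile, probs = 1 - a))
  }

  structure(list(
    turns = turns, casts = casts,
    turn_rate_vs_bearing = data.frame(
      bearing = bearing_mid_abs, n_turns = turn_counts_abs,
      run_time_s = run_time_abs,
      rate = ifelse(run_time_abs > 0, turn_counts_abs / run_time_abs, NA)),
    left_turn_prob_vs_bearing = data.frame(bearing = bearing_mid,
                                           p_left = left_prob),
    reorientation_vs_bearing = data.frame(
      bearing = bearing_mid,
      mean_dadt = ifelse(run_reo_n > 0, run_reo_sum / run_reo_n, NA)),
    run_lengths = run_lengths,
    pre_turn_bearing = if (nrow(turns) > 0) abs(turns$bearing_start) else numeric(0),
    bearing_by_class = if (nrow(turns) > 0)
      split(abs(turns$bearing_start), turns$class) else list(),
    casts_per_turn = casts_per_turn,
    cast_patterns = sort(table(per_turn_patterns), decreasing = TRUE),
    first_cast_to_high = if (length(first_classes) > 0)
      mean(first_classes == "to_high") else NA_real_,
    n_first_casts = length(first_classes),
    distance_to_source = dist_curve,
    n_larvae = length(trajs)),
    class = "larva_stats")
}

#' @export
print.larva_stats <- function(x, ...) {
  cat("<larva_stats>", x$n_larvae, "larvae,", nrow(x$turns), "turns,",
      nrow(x$casts), "head casts\n")
  if (!is.na(x$first_cast_to_high))
    cat(sprintf("  first cast to high: %.1f%% of %d turns\n",
                100 * x$first_cast_to_high, x$n_first_casts))
  if (length(x$run_lengths) > 0)
    cat(sprintf("  mean run length: %.2fs\n", mean(x$run_lengths)))
  invisible(x)
}
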