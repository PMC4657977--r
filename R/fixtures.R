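## Synthetic trajectories with planted events ---------------------------------

#' Construct a synthetic trajectory with planted turns and head casts
#'
#' Builds a kinematically explicit trajectory for metric validation: the body
#' angle follows ramps of known rate and amplitude at the planted turn times,
#' the head angle traces triangular excursions of known peak at the planted
#' cast times, and the centroid integrates forward at constant speed. The
#' planted events are therefore exactly recoverable by the event detectors.
#'
#' @param duration total duration, s.
#' @param turns data.frame with columns `t` (start time, s), `delta` (net
#'   body-angle change, deg; positive = left) and optionally `rate` (deg/s,
#'   default 20).
#' @param casts data.frame with columns `t` (start time, s) and `peak`
#'   (signed peak head angle, deg; positive = left); swept at `cast_rate`.
#' @param dt sample interval, s.
#' @param v forward speed, mm/s.
#' @param alpha0 initial body angle, deg.
#' @param start initial centroid position, mm.
#' @param cast_rate head sweep speed for planted casts, deg/s.
#' @param L_head,L_body segment lengths, mm.
#' @return a `larva_trajectory` data.frame.
#' @export
synth_trajectory <- function(duration, turns = NULL, casts = NULL, dt = 0.1,
                             v = 1, alpha0 = 0, start = c(0, 0),
                             cast_rate = 240, L_head = 2, L_body = 2) {
  t <- seq(0, duration, by = dt)
  n <- length(t)
  alpha <- rep(alpha0, n)
  if (!is.null(turns) && nrow(turns) > 0) {
    if (is.null(turns$rate)) turns$rate <- rep(20, nrow(turns))
    for (j in seq_len(nrow(turns))) {
      ramp_dur <- abs(turns$delta[j]) / turns$rate[j]
      ramp <- pmin(pmax((t - turns$t[j]) / ramp_dur, 0), 1) * turns$delta[j]
      alpha <- alpha + ramp
    }
  }
  theta <- rep(0, n)
  if (!is.null(casts) && nrow(casts) > 0) {
    for (j in seq_len(nrow(casts))) {
      half <- abs(casts$peak[j]) / cast_rate
      tri <- pmax(0, 1 - abs(t - (casts$t[j] + half)) / half) * casts$peak[j]
      theta <- theta + tri
    }
  }
  # integrate the centroid along the body angle
  mx <- start[1] + c(0, cumsum(v * dt * cos(alpha[-n] * pi / 180)))
  my <- start[2] + c(0, cumsum(v * dt * sin(alpha[-n] * pi / 180)))
  hx <- mx + L_head * cos((alpha + theta) * pi / 180)
  hy <- my + L_head * sin((alpha + theta) * pi / 180)
  tx <- mx - L_body * cos(alpha * pi / 180)
  ty <- my - L_body * sin(alpha * pi / 180)
  df <- data.frame(t_s = t, head_x_mm = hx, head_y_mm = hy,
                   mid_x_mm = mx, mid_y_mm = my,
                   tail_x_mm = tx, tail_y_mm = ty,
                   alpha_deg = wrap_angle(alpha), theta_deg = theta,
                   mode = as.integer(abs(theta) > 37),
                   conc = 0, phi = 0, r_run = 0, r_cast = 0, r_wv = 0)
  structure(df, class = c("larva_trajectory", "data.frame"),
            seed = NA_integer_, larva_index = NA_integer_, cause = "none",
            dt = dt, stride = 1L, field_label = "synthetic",
            arena_label = "none")
}

#' Generate a deterministic test fixture file
#'
#' Writes either a gridded odour landscape (sampled from an analytic field)
#' or a synthetic trajectory CSV with planted events. Identical arguments and
#' seed always produce byte-identical files.
#'
#' @param kind `"landscape"` or `"trajectory"`.
#' @param spec for `"landscape"`: `list(field, extent, cell)`; for
#'   `"trajectory"`: arguments for [synth_trajectory()], or
#'   `list(duration, n_turns, n_casts)` to plant randomly drawn events.
#' @param path output file path.
#' @param seed seed for randomly drawn planted events.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(kind = c("landscape", "trajectory"), spec, path,
                             seed = 1) {
  kind <- match.arg(kind)
  if (kind == "landscape") {
    g <- sample_field_to_grid(spec$field, spec$extent, spec$cell %||% 1)
    write_odour_grid(g, path)
  } else {
    if (!is.null(spec$n_turns)) {
      spec <- with_seed(seed, {
        dur <- spec$duration %||% 120
        ts <- sort(runif(spec$n_turns, 5, dur - 10))
        spec$turns <- data.frame(t = ts,
                                 delta = sample(c(-1, 1), spec$n_turns, TRUE) *
                                   runif(spec$n_turns, 30, 90))
        if (!is.null(spec$n_casts)) {
          tc <- sort(runif(spec$n_casts, 2, dur - 5))
          spec$casts <- data.frame(t = tc,
                                   peak = sample(c(-1, 1), spec$n_casts, TRUE) *
                                     runif(spec$n_casts, 45, 115))
        }
        spec$n_turns <- NULL
        spec$n_casts <- NULL
        spec
      })
    }
    tr <- do.call(synth_trajectory, spec)
    write_trajectory_csv(tr, path)
  }
  invisible(path)
}
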