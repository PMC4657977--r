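## Time-stepping engine interface ---------------------------------------------

TRAJ_COLS <- c("t_s", "head_x_mm", "head_y_mm", "mid_x_mm", "mid_y_mm",
               "tail_x_mm", "tail_y_mm", "alpha_deg", "theta_deg", "mode",
               "conc", "phi", "r_run", "r_cast", "r_wv")

#' Truncation rules for simulated trajectories
#'
#' @return a truncation-rule object for [simulate_larva()] / [protocol()].
#' @name truncation
NULL

#' @rdname truncation
#' @export
trunc_none <- function() list(kind = 0L, p = numeric(0))

#' @describeIn truncation stop at the first contact of the head point with
#'   the arena wall (the wall response is not applied).
#' @export
trunc_wall <- function() list(kind = 1L, p = numeric(0))

#' @describeIn truncation stop once the centroid comes within `radius` mm of
#'   `point`.
#' @param point target point `c(x, y)`, mm.
#' @param radius capture radius, mm.
#' @export
trunc_radius <- function(point, radius) {
  stopifnot(radius > 0)
  list(kind = 2L, p = as.double(c(point, radius)))
}

#' @describeIn truncation stop once the centroid's projection on `direction`
#'   reaches `offset` (a line crossing).
#' @param direction axis for the line-crossing rule.
#' @param offset threshold along the axis, mm.
#' @export
trunc_line <- function(direction, offset) {
  u <- unit2(direction)
  list(kind = 3L, p = as.double(c(u, offset)))
}

trunc_cause_label <- function(code) {
  c("-1" = "nonfinite", "0" = "none", "1" = "wall", "2" = "radius",
    "3" = "line")[[as.character(code)]]
}

#' Simulate a single larva
#'
#' Steps the two-segment larva through the odour landscape: at every step the
#' concentration is sampled at the head tip, the perceptual signal appended
#' to the history, the three transition rates computed by kernel convolution
#' (in every behavioural state), and the run / head-cast state machine
#' advanced. Identical inputs and seed give a bit-identical trajectory.
#'
#' @param params a [larva_params()] object.
#' @param field an `odour_field`.
#' @param arena an `arena` (default: unbounded).
#' @param duration simulated time, s.
#' @param seed master seed (integer).
#' @param larva_index per-larva stream index; the RNG stream is derived from
#'   `(seed, larva_index)` so batches are order-independent.
#' @param init initial pose: `list(position = c(x, y), orientation = deg,
#'   theta = deg)`. The larva is laid out straight along `orientation` with
#'   the tail behind; `position` is the segment joint (centroid).
#' @param stride record every `stride`-th step (the final step is always
#'   recorded).
#' @param record `"full"` for the whole trajectory, `"final"` for the first
#'   and last recorded states only.
#' @param truncation a rule from [truncation].
#' @return a `larva_trajectory` data.frame with columns
#'   `r paste(TRAJ_COLS, collapse = ", ")`; `mode` is 0 during runs and 1
#'   during head casts. Attributes carry the seed, truncation cause and
#'   protocol metadata needed to replay the simulation.
#' @export
simulate_larva <- function(params, field, arena = arena_none(), duration,
                           seed = 1, larva_index = 0,
                           init = list(position = c(0, 0), orientation = 0,
                                       theta = 0),
                           stride = 1, record = c("full", "final"),
                           truncation = trunc_none()) {
  stopifnot(inherits(params, "larva_params"), inherits(field, "odour_field"),
            inherits(arena, "arena"), duration > 0, stride >= 1)
  record <- match.arg(record)
  pos <- init$position
  if (is.null(pos)) pos <- c(0, 0)
  orient <- if (is.null(init$orientation)) 0 else init$orientation
  theta0 <- if (is.null(init$theta)) 0 else init$theta
  if (!point_in_arena(arena, pos))
    stop("initial position lies outside the arena")
  res <- sim_larva_cpp(params_for_engine(params), kernels_for_engine(params),
                       field, arena, duration, as.double(seed),
                       as.integer(larva_index),
                       as.double(c(pos, orient, theta0)),
                       as.integer(stride), truncation, record == "full")
  if (res$cause == -1L)
    warning("simulation aborted on non-finite state (larva ", larva_index, ")")
  traj <- as.data.frame(res$traj)
  names(traj) <- TRAJ_COLS
  structure(traj,
            class = c("larva_trajectory", "data.frame"),
            seed = seed, larva_index = larva_index,
            cause = trunc_cause_label(res$cause),
            steps = res$steps, dt = params$dt, stride = stride,
            field_label = field$label, arena_label = arena$label)
}

#' @export
print.larva_trajectory <- function(x, ...) {
  cat(sprintf("<larva_trajectory> %d records, %.1fs simulated, end cause: %s\n",
              nrow(x), x$t_s[nrow(x)], attr(x, "cause")))
  invisible(x)
}

#' Plot a larva trajectory
#'
#' @param x a `larva_trajectory`.
#' @param what which body point(s) to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.larva_trajectory <- function(x, what = c("mid", "head", "tail"), ...) {
  what <- match.arg(what, several.ok = TRUE)
  cols <- c(mid = "black", head = "firebrick", tail = "grey60")
  graphics::plot(x$mid_x_mm, x$mid_y_mm, type = "n", asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)", ...)
  for (w in what)
    graphics::lines(x[[paste0(w, "_x_mm")]], x[[paste0(w, "_y_mm")]],
                    col = cols[[w]])
  invisible(x)
}

## Protocols and batches -------------------------------------------------------

#' Experiment protocol
#'
#' Bundles a landscape, arena, cohort size, duration, start distribution and
#' truncation/discard rules into a reproducible batch description.
#'
#' @param field an `odour_field`.
#' @param arena an `arena`.
#' @param n_larvae number of larvae (>= 1).
#' @param duration simulated time per larva, s.
#' @param start start-position rule: `start_square(centre, side)` or
#'   `start_line(from, to)` or `start_disc(centre, radius)`.
#' @param orientation start-orientation rule: `orient_uniform()`,
#'   `orient_toward(point, halfwidth)` or `orient_fixed(angle)`.
#' @param truncation a rule from [truncation].
#' @param discard `"none"` or `"non_arrivals"`: with `"non_arrivals"`,
#'   larvae whose run is not truncated by the rule are discarded and fresh
#'   larvae are simulated until `n_larvae` arrivals are collected (attempts
#'   capped at 50 per requested larva).
#' @param seed master seed.
#' @param stride recording stride.
#' @return a `protocol` object for [run_batch()].
#' @export
protocol <- function(field, arena, n_larvae, duration,
                     start = start_square(c(0, 0), 12),
                     orientation = orient_uniform(),
                     truncation = trunc_none(),
                     discard = c("none", "non_arrivals"),
                     seed = 1, stride = 1L) {
  stopifnot(inherits(field, "odour_field"), inherits(arena, "arena"),
            n_larvae >= 1, duration > 0)
  discard <- match.arg(discard)
  if (discard == "non_arrivals" && truncation$kind %in% c(0L, 1L))
    stop("discard = 'non_arrivals' needs a radius or line truncation rule")
  structure(list(field = field, arena = arena, n_larvae = as.integer(n_larvae),
                 duration = duration, start = start, orientation = orientation,
                 truncation = truncation, discard = discard,
                 seed = seed, stride = as.integer(stride)),
            class = "protocol")
}

#' Start-position rules
#' @param centre square/disc centre, mm.
#' @param side square side, mm.
#' @return a start-rule object for [protocol()].
#' @export
start_square <- function(centre, side) {
  stopifnot(side > 0)
  list(kind = "square", centre = centre, side = side)
}

#' @rdname start_square
#' @param from,to segment endpoints for a line start, mm.
#' @export
start_line <- function(from, to) list(kind = "line", from = from, to = to)

#' @rdname start_square
#' @param radius disc radius, mm.
#' @export
start_disc <- function(centre, radius) {
  stopifnot(radius > 0)
  list(kind = "disc", centre = centre, radius = radius)
}

#' Start-orientation rules
#' @return an orientation-rule object for [protocol()].
#' @export
orient_uniform <- function() list(kind = "uniform")

#' @rdname orient_uniform
#' @param point target point: orientations are drawn uniformly within
#'   `halfwidth` degrees of the direction towards `point`.
#' @param halfwidth half-range, deg.
#' @export
orient_toward <- function(point, halfwidth = 30) {
  list(kind = "toward", point = point, halfwidth = halfwidth)
}

#' @rdname orient_uniform
#' @param angle fixed orientation, deg.
#' @export
orient_fixed <- function(angle) list(kind = "fixed", angle = angle)

draw_start <- function(rule, n) {
  switch(rule$kind,
         square = cbind(runif(n, rule$centre[1] - rule$side / 2,
                              rule$centre[1] + rule$side / 2),
                        runif(n, rule$centre[2] - rule$side / 2,
                              rule$centre[2] + rule$side / 2)),
         line = {
           s <- runif(n)
           cbind(rule$from[1] + s * (rule$to[1] - rule$from[1]),
                 rule$from[2] + s * (rule$to[2] - rule$from[2]))
         },
         disc = {
           r <- rule$radius * sqrt(runif(n))
           a <- runif(n, 0, 2 * pi)
           cbind(rule$centre[1] + r * cos(a), rule$centre[2] + r * sin(a))
         })
}

draw_orientation <- function(rule, pos) {
  n <- nrow(pos)
  switch(rule$kind,
         uniform = runif(n, -180, 180),
         toward = {
           base <- atan2(rule$point[2] - pos[, 2], rule$point[1] - pos[, 1]) * 180 / pi
           base + runif(n, -rule$halfwidth, rule$halfwidth)
         },
         fixed = rep(rule$angle, n))
}

#' Run a batch of independent larvae under a protocol
#'
#' Start poses are drawn from the protocol's master seed; each larva then
#' gets an independent RNG stream derived from `(seed, larva index)`, so the
#' batch is reproducible and independent of execution order.
#'
#' @param prot a [protocol()].
#' @param params a [larva_params()] object.
#' @param record `"full"` to keep whole trajectories, `"final"` to keep only
#'   initial/final states (lighter; enough for preference/dispersal
#'   measures).
#' @return a `larva_batch`: list with `trajectories` (when `record = "full"`),
#'   `final` (data.frame of final states, one row per larva, with start pose
#'   and truncation cause), `n_discarded`, and the protocol and params used.
#' @export
run_batch <- function(prot, params, record = c("full", "final")) {
  stopifnot(inherits(prot, "protocol"), inherits(params, "larva_params"))
  record <- match.arg(record)
  n <- prot$n_larvae
  max_attempts <- if (prot$discard == "non_arrivals") 50L * n else n
  trajs <- vector("list", n)
  finals <- vector("list", n)
  kept <- 0L
  attempted <- 0L
  discarded <- 0L
  # start poses drawn attempt-by-attempt from per-attempt derived seeds, so
  # a resimulated (discarded) attempt never shifts later larvae's draws
  draws <- local({
    env <- new.env()
    env$i <- 0L
    env
  })
  next_pose <- function() {
    draws$i <- draws$i + 1L
    with_seed(prot$seed + draws$i, {
      repeat {
        pos <- draw_start(prot$start, 1L)
        if (point_in_arena(prot$arena, pos)) break
      }
      list(pos = drop(pos), orient = draw_orientation(prot$orientation, pos))
    })
  }
  while (kept < n && attempted < max_attempts) {
    attempted <- attempted + 1L
    pose <- next_pose()
    tr <- simulate_larva(params, prot$field, prot$arena, prot$duration,
                         seed = prot$seed, larva_index = attempted - 1L,
                         init = list(position = pose$pos,
                                     orientation = pose$orient, theta = 0),
                         stride = prot$stride, record = record,
                         truncation = prot$truncation)
    arrived <- attr(tr, "cause") %in% c("radius", "line")
    if (prot$discard == "non_arrivals" && !arrived) {
      discarded <- discarded + 1L
      next
    }
    kept <- kept + 1L
    fin <- tr[nrow(tr), , drop = FALSE]
    fin$larva <- attempted - 1L
    fin$cause <- attr(tr, "cause")
    fin$start_x <- pose$pos[1]
    fin$start_y <- pose$pos[2]
    fin$start_orientation <- pose$orient
    finals[[kept]] <- fin
    if (record == "full") trajs[[kept]] <- tr
  }
  if (kept == 0L)
    stop("no larvae survived the discard rule (", attempted, " attempts)")
  if (kept < n)
    warning("only ", kept, " of ", n, " larvae arrived within the attempt cap")
  structure(list(trajectories = if (record == "full") trajs[seq_len(kept)],
                 final = do.call(rbind, finals[seq_len(kept)]),
                 n_discarded = discarded, n_attempted = attempted,
                 protocol = prot, params = params),
            class = "larva_batch")
}

#' @export
print.larva_batch <- function(x, ...) {
  cat(sprintf("<larva_batch> %d larvae, %.0fs each, field %s, arena %s\n",
              nrow(x$final), x$protocol$duration, x$protocol$field$label,
              x$protocol$arena$label))
  if (x$n_discarded > 0)
    cat("  discarded non-arrivals:", x$n_discarded, "\n")
  invisible(x)
}

#' Final centroid positions of a batch
#' @param batch a `larva_batch`.
#' @return n x 2 matrix of final centroid (joint) positions, mm.
#' @export
final_positions <- function(batch) {
  stopifnot(inherits(batch, "larva_batch"))
  as.matrix(batch$final[, c("mid_x_mm", "mid_y_mm")])
}

## Trajectory file I/O ---------------------------------------------------------

#' Write a trajectory to CSV (with a JSON metadata sidecar)
#'
#' @param traj a `larva_trajectory`.
#' @param path CSV path; metadata is written to `<path>.json`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "larva_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(seed = attr(traj, "seed"), larva_index = attr(traj, "larva_index"),
               cause = attr(traj, "cause"), dt = attr(traj, "dt"),
               stride = attr(traj, "stride"),
               field = attr(traj, "field_label"), arena = attr(traj, "arena_label"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#' @param path CSV path.
#' @return a `larva_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(identical(names(df), TRAJ_COLS))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(df, class = c("larva_trajectory", "data.frame"),
            seed = meta$seed, larva_index = meta$larva_index,
            cause = meta$cause, dt = meta$dt %||% median(diff(df$t_s)),
            stride = meta$stride %||% 1L,
            field_label = meta$field %||% "", arena_label = meta$arena %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
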