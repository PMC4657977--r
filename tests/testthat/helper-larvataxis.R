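# Shared helpers for the test suite.

# Segment lengths along a trajectory (should equal L_head / L_body).
segment_lengths <- function(tr) {
  list(head = sqrt((tr$head_x_mm - tr$mid_x_mm)^2 +
                   (tr$head_y_mm - tr$mid_y_mm)^2),
       body = sqrt((tr$tail_x_mm - tr$mid_x_mm)^2 +
                   (tr$tail_y_mm - tr$mid_y_mm)^2))
}

# Completed run durations (s) from the recorded mode column: maximal RUN
# blocks that end in a transition to head casting.
completed_run_durations <- function(tr, dt = 0.1) {
  r <- rle(tr$mode)
  runs <- r$lengths[r$values == 0]
  if (tr$mode[nrow(tr)] == 0 && length(runs) > 0) runs <- runs[-length(runs)]
  runs * dt
}

# theta at the moment each head-cast episode terminates (the first RUN row
# after a CAST block carries the terminal head angle).
cast_termination_angles <- function(tr) {
  m <- tr$mode
  k <- which(m[-length(m)] == 1 & m[-1] == 0)
  tr$theta_deg[k + 1]
}

uniform_larva <- function(duration = 100, seed = 1, index = 0, params = larva_params(),
                          ...) {
  simulate_larva(params, odour_field_uniform(), duration = duration,
                 seed = seed, larva_index = index, ...)
}
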