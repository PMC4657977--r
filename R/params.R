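## Larva parameters ------------------------------------------------------------

#' Larva parameters
#'
#' All constants of the behavioural model with their default values: the
#' simulation time step, forward speed, head-cast geometry and speeds, base
#' transition rates, the three transition kernels, segment lengths and wall
#' response. Defaults are the tuned reference parameter set; any field can be
#' overridden.
#'
#' @param dt simulation time step, s. The default kernel magnitudes are tied
#'   to dt = 0.1 s; see [sample_kernel()].
#' @param v_forward forward crawling speed during runs, mm/s.
#' @param t_min_run minimum run duration (refractory period after a
#'   transition to running during which the run cannot terminate), s.
#' @param theta_max_head_cast head cast range, deg.
#' @param theta_min_head_cast minimum head angle at which a head cast may
#'   terminate, deg.
#' @param cast_speed rotational speed of head casts, deg/s.
#' @param theta_max_weathervane_cast weathervane cast range, deg.
#' @param weathervane_cast_speed rotational speed of weathervane casts, deg/s.
#' @param r_run_termination_base run termination base rate, 1/s.
#' @param r_cast_termination_base cast termination base rate, 1/s.
#' @param r_weathervane_cast_termination_base weathervane cast pause base
#'   rate, 1/s.
#' @param r_weathervane_cast_resume weathervane cast resumption rate, 1/s
#'   (constant, not modulated).
#' @param kernel_run_terminate,kernel_cast_terminate,kernel_weathervane the
#'   three transition kernels ([kernel_linear()] /
#'   [kernel_differenced_mean()]).
#' @param L_head,L_body head and body segment lengths, mm. The two segments
#'   are of equal length; 2 mm each puts the whole body at a typical larval
#'   scale.
#' @param wall_deflection head deflection per contact step when running into
#'   a wall, deg.
#' @param weathervane_casting logical; FALSE removes weathervane casting
#'   altogether (head orientation fixed in the world during runs). Distinct
#'   from zeroing the weathervane kernel, which keeps the casts but removes
#'   their sensory modulation.
#' @param first_cast_bias logical; TRUE (default) starts the first head cast
#'   after run termination on the side the head is currently pointing,
#'   FALSE casts left/right with equal probability.
#' @return a `larva_params` object.
#' @export
larva_params <- function(dt = 0.1,
                         v_forward = 1,
                         t_min_run = 1,
                         theta_max_head_cast = 120,
                         theta_min_head_cast = 37,
                         cast_speed = 240,
                         theta_max_weathervane_cast = 20,
                         weathervane_cast_speed = 60,
                         r_run_termination_base = 0.148,
                         r_cast_termination_base = 2,
                         r_weathervane_cast_termination_base = 2,
                         r_weathervane_cast_resume = 1,
                         kernel_run_terminate = kernel_linear(20, 2, -2),
                         kernel_cast_terminate = kernel_linear(0.5, 0, 150),
                         kernel_weathervane = kernel_differenced_mean(1, 10, 30),
                         L_head = 2,
                         L_body = 2,
                         wall_deflection = 15,
                         weathervane_casting = TRUE,
                         first_cast_bias = TRUE) {
  p <- structure(as.list(environment()), class = "larva_params")
  validate_larva_params(p)
  p
}

validate_larva_params <- function(p) {
  stopifnot(inherits(p, "larva_params"))
  with(p, {
    stopifnot(dt > 0, v_forward > 0, t_min_run >= 0,
              theta_min_head_cast < theta_max_head_cast,
              theta_max_head_cast > 0, theta_min_head_cast > 0,
              cast_speed > 0, theta_max_weathervane_cast > 0,
              weathervane_cast_speed > 0,
              r_run_termination_base >= 0, r_cast_termination_base >= 0,
              r_weathervane_cast_termination_base >= 0,
              r_weathervane_cast_resume >= 0,
              L_head > 0, L_body > 0, wall_deflection >= 0)
    stopifnot(inherits(kernel_run_terminate, "kernel_spec"),
              inherits(kernel_cast_terminate, "kernel_spec"),
              inherits(kernel_weathervane, "kernel_spec"))
  })
  if (abs(p$dt - 0.1) > 1e-12)
    warning("default kernel magnitudes are calibrated for dt = 0.1 s; ",
            "rescale the kernels if you change dt", call. = FALSE)
  invisible(p)
}

#' Enable, disable or rescale the three sensory mechanisms
#'
#' Disabling a mechanism zeroes its kernel so the associated transition
#' happens at its base rate, unaffected by the odour gradient; the
#' behavioural transition itself is never removed. Scaling multiplies the
#' kernel weights (slope); a negative scaling reverses the modulation.
#'
#' @param params a `larva_params` object.
#' @param run_term,cast_term,weathervane logical enable flags for the three
#'   mechanisms (run termination bias, cast termination bias, weathervane
#'   bias).
#' @param scaling a single multiplier applied to all enabled kernels, or a
#'   named numeric `c(run_term =, cast_term =, weathervane =)`.
#' @return the modified `larva_params`.
#' @export
configure_mechanisms <- function(params, run_term = TRUE, cast_term = TRUE,
                                 weathervane = TRUE, scaling = 1) {
  stopifnot(inherits(params, "larva_params"))
  s <- if (length(scaling) == 1)
    c(run_term = scaling, cast_term = scaling, weathervane = scaling)
  else {
    stopifnot(all(c("run_term", "cast_term", "weathervane") %in% names(scaling)))
    scaling
  }
  if (!run_term) s[["run_term"]] <- 0
  if (!cast_term) s[["cast_term"]] <- 0
  if (!weathervane) s[["weathervane"]] <- 0
  params$kernel_run_terminate <- scale_kernel(params$kernel_run_terminate, s[["run_term"]])
  params$kernel_cast_terminate <- scale_kernel(params$kernel_cast_terminate, s[["cast_term"]])
  params$kernel_weathervane <- scale_kernel(params$kernel_weathervane, s[["weathervane"]])
  params
}

#' @export
print.larva_params <- function(x, ...) {
  cat("<larva_params>\n")
  cat(sprintf("  dt %gs, v %g mm/s, min run %gs, segments %g + %g mm\n",
              x$dt, x$v_forward, x$t_min_run, x$L_head, x$L_body))
  cat(sprintf("  head cast: %g..%g deg at %g deg/s; weathervane: %g deg at %g deg/s\n",
              x$theta_min_head_cast, x$theta_max_head_cast, x$cast_speed,
              x$theta_max_weathervane_cast, x$weathervane_cast_speed))
  cat(sprintf("  base rates (1/s): run term %g, cast term %g, wv pause %g, wv resume %g\n",
              x$r_run_termination_base, x$r_cast_termination_base,
              x$r_weathervane_cast_termination_base, x$r_weathervane_cast_resume))
  print(x$kernel_run_terminate)
  print(x$kernel_cast_terminate)
  print(x$kernel_weathervane)
  invisible(x)
}

# Flatten params for the compiled engine.
params_for_engine <- function(p) {
  list(dt = p$dt, v_forward = p$v_forward, t_min_run = p$t_min_run,
       theta_max_head_cast = p$theta_max_head_cast,
       theta_min_head_cast = p$theta_min_head_cast,
       cast_speed = p$cast_speed,
       theta_max_weathervane_cast = p$theta_max_weathervane_cast,
       weathervane_cast_speed = p$weathervane_cast_speed,
       r_run_termination_base = p$r_run_termination_base,
       r_cast_termination_base = p$r_cast_termination_base,
       r_weathervane_cast_termination_base = p$r_weathervane_cast_termination_base,
       r_weathervane_cast_resume = p$r_weathervane_cast_resume,
       L_head = p$L_head, L_body = p$L_body,
       wall_deflection = p$wall_deflection,
       weathervane_casting = as.double(p$weathervane_casting),
       first_cast_bias = as.double(p$first_cast_bias))
}

kernels_for_engine <- function(p) {
  list(run = sample_kernel(p$kernel_run_terminate, p$dt),
       cast = sample_kernel(p$kernel_cast_terminate, p$dt),
       weathervane = sample_kernel(p$kernel_weathervane, p$dt))
}
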