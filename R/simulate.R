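#' Dosing schedule for boundary species
#'
#' A schedule is an ordered set of (time, species, amount) events that reset
#' a boundary species (insulin or extracellular ROS) to a new particle
#' number. Between events boundary amounts are constant.
#'
#' @param time Event times (min), non-decreasing.
#' @param species Boundary species names.
#' @param amount New amounts (particles).
#' @return data.frame of class `insox_schedule`.
#' @export
schedule <- function(time = numeric(), species = character(),
                     amount = numeric()) {
  df <- data.frame(time = time, species = species, amount = amount,
                   stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("insox_schedule", "data.frame")
  df
}

#' Convert an insulin concentration to model particles
#'
#' Insulin lives in the extracellular compartment (8.3e-12 l, scale 1):
#' 100 nM corresponds to 5e5 particles.
#'
#' @param nM Concentration in nmol/l.
#' @return Particle number.
#' @export
insulin_nM_to_particles <- function(nM) {
  nM * 1e-9 * 6.02214076e23 * 8.3e-12
}

#' Convert an extracellular ROS concentration to model particles
#'
#' Extracellular ROS is a scale-1000 species: 10 uM corresponds to 5e4
#' model particles.
#'
#' @param uM Concentration in umol/l.
#' @return Model particle number.
#' @export
ros_uM_to_particles <- function(uM) {
  uM * 1e-6 * 6.02214076e23 * 8.3e-12 / 1000
}

#' Simulation configuration
#'
#' @param rtol,atol Relative/absolute solver tolerances (atol in particles).
#' @param method deSolve integrator; "lsoda" switches automatically to a
#'   stiff BDF scheme, which this network requires (ROS relaxes in ~0.01 s
#'   while protein turnover takes hours).
#' @param maxsteps Maximum internal steps per output interval.
#' @return List of class `insox_sim_config`.
#' @export
sim_config <- function(rtol = 1e-8, atol = 1e-6, method = "lsoda",
                       maxsteps = 50000) {
  stopifnot(rtol > 0, atol > 0)
  structure(list(rtol = rtol, atol = atol, method = method,
                 maxsteps = maxsteps), class = "insox_sim_config")
}

#' Integrate a model over time with a dosing schedule
#'
#' Deterministic stiff ODE integration of the assembled network in particle
#' numbers. Schedule events replace boundary-species values at the stated
#' times; integration restarts cleanly at each event. Boundary species have
#' zero derivative, so they are bitwise constant between events.
#'
#' @param model An [new_model()] object (or the result of [assemble_ode()]).
#' @param t_end End time (min), > 0.
#' @param sched Optional [schedule()].
#' @param init Optional named vector overriding initial amounts (partial
#'   overrides allowed).
#' @param times Optional explicit output grid; defaults to 1-min resolution
#'   (0.01-min when `t_end` <= 10).
#' @param config [sim_config()].
#' @return `insox_sim_result`: list with `times`, `amounts` (time x species
#'   matrix), `model`, `schedule`, `diagnostics`.
#' @export
simulate_model <- function(model, t_end, sched = NULL, init = NULL,
                           times = NULL, config = sim_config()) {
  stopifnot(t_end > 0)
  ode_sys <- if (inherits(model, "insox_model")) assemble_ode(model) else model
  state <- ode_sys$state0
  if (!is.null(init)) {
    unknown <- setdiff(names(init), names(state))
    if (length(unknown)) {
      stop("init overrides unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    state[names(init)] <- init
  }
  if (is.null(times)) {
    dt <- if (t_end <= 10) 0.01 else 1
    times <- seq(0, t_end, by = dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  }
  events <- NULL
  if (!is.null(sched) && nrow(sched)) {
    bnd <- model_boundary_names(ode_sys, model)
    bad <- setdiff(unique(sched$species), bnd)
    if (length(bad)) {
      stop("schedule addresses non-boundary species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ev <- sched[sched$time <= t_end, , drop = FALSE]
    # events at t = 0 are applied to the initial state directly
    at0 <- ev$time <= 0
    if (any(at0)) state[ev$species[at0]] <- ev$amount[at0]
    ev <- ev[!at0, , drop = FALSE]
    if (nrow(ev)) {
      events <- list(data = data.frame(var = ev$species, time = ev$time,
                                       value = ev$amount,
                                       method = "replace",
                                       stringsAsFactors = FALSE))
      times <- sort(unique(c(times, ev$time)))
    }
  }
  f <- function(t, y, parms) list(ode_sys$derivs(t, y))
  jf <- function(t, y, parms) ode_sys$jacobian(t, y)
  out <- deSolve::ode(y = state, times = times, func = f, parms = NULL,
                      method = config$method, rtol = config$rtol,
                      atol = config$atol, maxsteps = config$maxsteps,
                      jacfunc = jf, jactype = "fullusr",
                      events = events)
  diag <- attributes(out)[c("istate", "rstate")]
  if (attr(out, "istate")[1] < 0) {
    stop("solver failed (istate ", attr(out, "istate")[1],
         "); last good time ", max(out[, "time"]), call. = FALSE)
  }
  structure(list(times = out[, "time"],
                 amounts = out[, -1, drop = FALSE],
                 model = if (inherits(model, "insox_model")) model else NULL,
                 schedule = sched, diagnostics = diag),
            class = "insox_sim_result")
}

model_boundary_names <- function(ode_sys, model) {
  if (inherits(model, "insox_model")) {
    model$species$name[model$species$boundary]
  } else {
    names(ode_sys$state0)
  }
}

#' @export
print.insox_sim_result <- function(x, ...) {
  cat("<insox_sim_result> ", length(x$times), " time points x ",
      ncol(x$amounts), " species, t in [", min(x$times), ", ",
      max(x$times), "] min\n", sep = "")
  invisible(x)
}

#' Final state of a simulation
#' @param result An `insox_sim_result`.
#' @return Named numeric vector.
#' @export
final_state <- function(result) {
  result$amounts[nrow(result$amounts), ]
}

#' Run a model to (numerical) steady state
#'
#' Integrates with constant boundary values until the relative change of
#' every non-boundary species over the last quarter of the run is below
#' `tol`, doubling the horizon up to `t_max`.
#'
#' @param model Model or assembled system.
#' @param init Optional initial-state overrides.
#' @param t_start Initial horizon (min).
#' @param t_max Maximum horizon (min).
#' @param tol Relative-change tolerance.
#' @param config Solver configuration.
#' @return Named steady-state vector (attribute `t_used` records the horizon).
#' @export
run_to_steady <- function(model, init = NULL, t_start = 500, t_max = 16000,
                          tol = 1e-6, config = sim_config()) {
  t_end <- t_start
  repeat {
    res <- simulate_model(model, t_end, init = init,
                          times = seq(0, t_end, length.out = 101),
                          config = config)
    a <- res$amounts
    i0 <- nrow(a) - 25L
    ref <- pmax(abs(a[nrow(a), ]), 1e-3)
    drift <- max(abs(a[nrow(a), ] - a[i0, ]) / ref)
    if (drift < tol || t_end >= t_max) {
      out <- final_state(res)
      attr(out, "t_used") <- t_end
      attr(out, "drift") <- drift
      return(out)
    }
    t_end <- t_end * 2
  }
}

#' Tidy a simulation result
#'
#' @param result An `insox_sim_result`.
#' @param species Optional subset of species.
#' @param concentrations Add a molar concentration column (requires the
#'   result to carry its model).
#' @return data.frame with columns time, species, amount (and concentration).
#' @export
as_tidy_result <- function(result, species = NULL, concentrations = FALSE) {
  a <- result$amounts
  if (!is.null(species)) a <- a[, species, drop = FALSE]
  df <- data.frame(
    time = rep(result$times, times = ncol(a)),
    species = rep(colnames(a), each = nrow(a)),
    amount = as.vector(a),
    stringsAsFactors = FALSE)
  if (concentrations) {
    if (is.null(result$model)) stop("result carries no model", call. = FALSE)
    conc <- numeric(nrow(df))
    for (sp in unique(df$species)) {
      i <- df$species == sp
      conc[i] <- particles_to_concentration(df$amount[i], sp, result$model)
    }
    df$concentration <- conc
  }
  df
}
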