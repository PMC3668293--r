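#' Scenario protocols
#'
#' Scripted experiments over the assembled model: insulin steps,
#' dose-response sweeps, fasting, insulin x oxidant interaction and
#' oxidative-stress preconditioning. Unless stated otherwise a scenario
#' starts from the printed initial particle numbers, settles briefly at its
#' basal boundary values (insulin 0, external ROS 0) and then applies the
#' stimulus. "Glucose uptake" is read out throughout as the cell-surface
#' GLUT4 fraction.
#'
#' @name scenarios
NULL

.basal_boundaries <- function(insulin_nM = 0, ros_uM = 0) {
  c(Ins = insulin_nM_to_particles(insulin_nM),
    extracellular_ROS = ros_uM_to_particles(ros_uM))
}

#' Fractional readouts of the signalling moieties
#'
#' Derived quantities used across figures: active fractions of each conserved
#' pool, the IRS1-PI3K complex as a fraction of total PI3K, the PIP3 share of
#' the lipid pool, the surface-GLUT4 fraction, oxidized phosphatase
#' fractions, and FOXO localization fractions.
#'
#' @param state Named state vector (a row of `$amounts` or [final_state()]).
#' @return Named numeric vector of fractions.
#' @export
readout_fractions <- function(state) {
  s <- as.list(state)
  foxo <- grep("_Foxo1_", names(state), value = TRUE)
  foxo_tot <- sum(state[foxo])
  dna <- sum(state[grep("^DNAbound_", foxo, value = TRUE)])
  c(pi3k_complex = s$IRS1_PI3K / (s$IRS1_PI3K + s$PI3K),
    pip3 = s$PIP3 / (s$PIP3 + s$PIP2),
    akt_active = s$Akt_P / (s$Akt_P + s$Akt),
    pkc_active = s$PKC_P / (s$PKC_P + s$PKC),
    as160_active = s$AS160_P / (s$AS160_P + s$AS160),
    glut4_surface = s$cellsurface_GLUT4 /
      (s$cellsurface_GLUT4 + s$cytoplasm_GLUT4),
    irs1_tyrp = s$IRS1_TyrP /
      (s$IRS1 + s$IRS1_TyrP + s$IRS1_PolySerP + s$IRS1_TyrP_PolySerP +
         s$IRS1_PI3K),
    ptp1b_ox = s$PTP1B_ox / (s$PTP1B + s$PTP1B_ox),
    pten_ox = s$PTEN_ox / (s$PTEN + s$PTEN_ox),
    jnk_active = s$JNK_P / (s$JNK + s$JNK_P),
    ikk_active = s$IKK_P / (s$IKK + s$IKK_P),
    foxo_dna_fraction = if (foxo_tot > 0) dna / foxo_tot else NA_real_)
}

#' Insulin step response
#'
#' Settles the model at zero insulin and zero external oxidant for
#' `t_settle` minutes, then steps insulin to `insulin_nM` and integrates for
#' `t_end` minutes, returning fractional readouts over time.
#'
#' @param insulin_nM Insulin step (nM).
#' @param t_end Post-step duration (min).
#' @param t_settle Basal settling time (min).
#' @param model Optional prebuilt model (defaults to [build_full_model()]).
#' @param dt Output resolution (min).
#' @param config Solver configuration.
#' @return data.frame: time (min, 0 = step) plus the [readout_fractions()]
#'   columns.
#' @export
run_insulin_step <- function(insulin_nM, t_end = 60, t_settle = 15,
                             model = build_full_model(), dt = 0.25,
                             config = sim_config()) {
  base <- simulate_model(model, t_settle, init = .basal_boundaries(0, 0),
                         times = c(0, t_settle), config = config)
  s0 <- final_state(base)
  s0["Ins"] <- insulin_nM_to_particles(insulin_nM)
  res <- simulate_model(model, t_end, init = s0,
                        times = seq(0, t_end, by = dt), config = config)
  fr <- t(apply(res$amounts, 1, readout_fractions))
  data.frame(time = res$times, fr)
}

#' Dose-response sweep over insulin
#'
#' For each insulin level, settles basally then integrates `t_measure`
#' minutes at that level and reports the readouts at `t_measure` (the
#' near-plateau of the rapid signalling layer).
#'
#' @param levels_nM Ascending insulin levels (nM).
#' @param t_measure Measurement time after the step (min).
#' @param model Optional prebuilt model.
#' @param t_settle Basal settling time (min).
#' @param config Solver configuration.
#' @return data.frame: insulin_nM plus readout columns, and the half-maximal
#'   dose per readout as attribute `half_max_dose`.
#' @export
run_dose_response <- function(levels_nM, t_measure = 30,
                              model = build_full_model(), t_settle = 15,
                              config = sim_config()) {
  stopifnot(!is.unsorted(levels_nM))
  base <- simulate_model(model, t_settle, init = .basal_boundaries(0, 0),
                         times = c(0, t_settle), config = config)
  s0 <- final_state(base)
  rows <- lapply(levels_nM, function(nm) {
    s <- s0
    s["Ins"] <- insulin_nM_to_particles(nm)
    res <- simulate_model(model, t_measure, init = s,
                          times = c(0, t_measure / 2, t_measure),
                          config = config)
    readout_fractions(final_state(res))
  })
  out <- data.frame(insulin_nM = levels_nM, do.call(rbind, rows))
  attr(out, "half_max_dose") <- vapply(
    setdiff(names(out), "insulin_nM"),
    function(cl) half_max_dose(out$insulin_nM, out[[cl]]), numeric(1))
  out
}

#' Half-maximal dose of a monotone dose-response curve
#'
#' Linear interpolation of the dose at which the response crosses the
#' midpoint between its value at the lowest and highest dose.
#'
#' @param dose Dose vector (ascending).
#' @param response Response vector.
#' @return Interpolated half-maximal dose (NA if the curve is flat).
#' @export
half_max_dose <- function(dose, response) {
  lo <- response[1]; hi <- response[length(response)]
  if (!is.finite(lo) || !is.finite(hi) || abs(hi - lo) < 1e-12) {
    return(NA_real_)
  }
  mid <- (lo + hi) / 2
  above <- if (hi > lo) response >= mid else response <= mid
  i <- which(above)[1]
  if (is.na(i) || i == 1) return(dose[1])
  f <- (mid - response[i - 1]) / (response[i] - response[i - 1])
  dose[i - 1] + f * (dose[i] - dose[i - 1])
}

#' Standard pre-equilibration for long-run scenarios
#'
#' Two-stage recipe: `days` days of diurnal insulin variation (meal peaks
#' over a 0.2 nM fasting baseline), then two days at constant 0.2 nM, with
#' no external oxidant. Long-term scenarios (fasting, preconditioning,
#' oxidant dose bars) start from the state this returns.
#'
#' @param model Optional prebuilt model.
#' @param days Diurnal days (default 5).
#' @param config Solver configuration.
#' @return Named state vector at the end of the recipe.
#' @export
equilibrate_standard <- function(model = build_full_model(), days = 5,
                                 config = sim_config()) {
  sched <- generate_diurnal_insulin(days = days)
  span <- attr(sched, "t_span")
  res <- simulate_model(model, span, sched = sched,
                        init = c(extracellular_ROS = 0),
                        times = seq(0, span, length.out = max(25, days * 8)),
                        config = config)
  s <- final_state(res)
  s["Ins"] <- insulin_nM_to_particles(0.2)
  res2 <- simulate_model(model, 2880, init = s,
                         times = seq(0, 2880, length.out = 25),
                         config = config)
  final_state(res2)
}

#' Fasting (insulin withdrawal) scenario
#'
#' Runs the model at zero insulin for `t_fast_min`, tracking total insulin
#' receptor (all surface + internalized forms), and measures GLUT4
#' dose-response curves at the start and end of the fast.
#'
#' @param t_fast_min Fast duration (min), e.g. 2880 for 48 h.
#' @param probe_levels_nM Insulin levels for the dose-response probes.
#' @param model Optional prebuilt model.
#' @param base_state Fed baseline state; defaults to the two-stage
#'   [equilibrate_standard()] recipe.
#' @param config Solver configuration.
#' @return List: `inr_trajectory` (data.frame time, total InR),
#'   `dr_before`, `dr_after` (dose-response tables), `inr_fold`
#'   (total InR at end / start).
#' @export
run_fasting <- function(t_fast_min = 2880,
                        probe_levels_nM = c(0.01, 0.03, 0.1, 0.3, 1, 3, 10),
                        model = build_full_model(),
                        base_state = NULL,
                        config = sim_config()) {
  inr_forms <- c("InR", "InR_Ins", "InR_Ins_P", "InR_Ins2_P",
                 "cytoplasm_InR", "cytoplasm_InR_Ins_P",
                 "cytoplasm_InR_Ins2_P")
  start <- if (is.null(base_state)) {
    equilibrate_standard(model, config = config)
  } else base_state
  start["Ins"] <- 0
  dr_probe <- function(state0) {
    rows <- lapply(probe_levels_nM, function(nm) {
      s <- state0
      s["Ins"] <- insulin_nM_to_particles(nm)
      res <- simulate_model(model, 30, init = s, times = c(0, 15, 30),
                            config = config)
      readout_fractions(final_state(res))
    })
    data.frame(insulin_nM = probe_levels_nM, do.call(rbind, rows))
  }
  if (t_fast_min <= 0) {
    traj <- data.frame(time = 0, inr_total = sum(start[inr_forms]))
    dr0 <- dr_probe(start)
    return(list(inr_trajectory = traj, dr_before = dr0, dr_after = dr0,
                inr_fold = 1))
  }
  res <- simulate_model(model, t_fast_min, init = start,
                        times = seq(0, t_fast_min, length.out = 145),
                        config = config)
  inr_tot <- rowSums(res$amounts[, inr_forms, drop = FALSE])
  list(
    inr_trajectory = data.frame(time = res$times, inr_total = inr_tot),
    dr_before = dr_probe(start),
    dr_after = dr_probe(final_state(res)),
    inr_fold = inr_tot[length(inr_tot)] / inr_tot[1])
}

#' Insulin x oxidative-stress interaction
#'
#' Applies the four combinations of insulin (0 / `insulin_nM`) and external
#' ROS (0 / `ros_uM`) from a common basal state and reports the
#' surface-GLUT4 proxy for glucose uptake at `t_measure`. The default
#' 240-min exposure lets the stress-kinase feedback on IRS1 (serine
#' phosphorylation and accelerated turnover) develop, as in the multi-hour
#' uptake experiments this protocol mirrors.
#'
#' @param insulin_nM Insulin dose (default 10 nM).
#' @param ros_uM External hydrogen peroxide dose (default 5 uM).
#' @param t_measure Measurement time (min).
#' @param model Optional prebuilt model.
#' @param config Solver configuration.
#' @return data.frame with condition labels and readouts.
#' @export
run_insulin_ros <- function(insulin_nM = 10, ros_uM = 5, t_measure = 240,
                            model = build_full_model(),
                            config = sim_config()) {
  base <- simulate_model(model, 15, init = .basal_boundaries(0, 0),
                         times = c(0, 15), config = config)
  s0 <- final_state(base)
  conds <- data.frame(
    condition = c("basal", "ros", "insulin_ros", "insulin"),
    insulin_nM = c(0, 0, insulin_nM, insulin_nM),
    ros_uM = c(0, ros_uM, ros_uM, 0), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    s <- s0
    s["Ins"] <- insulin_nM_to_particles(conds$insulin_nM[i])
    s["extracellular_ROS"] <- ros_uM_to_particles(conds$ros_uM[i])
    res <- simulate_model(model, t_measure, init = s,
                          times = seq(0, t_measure, by = 5), config = config)
    readout_fractions(final_state(res))
  })
  cbind(conds, do.call(rbind, rows))
}

#' SOD2 response to graded external oxidant
#'
#' 16-hour exposure to each external ROS level at constant low insulin,
#' reporting SOD2 relative to the zero-stress control.
#'
#' @param ros_levels_uM External ROS levels (uM), including 0.
#' @param insulin_nM Constant insulin (default 2 nM).
#' @param t_measure Exposure duration (min; default 960 = 16 h).
#' @param model Optional prebuilt model.
#' @param base_state Baseline state (default [equilibrate_standard()]).
#' @param config Solver configuration.
#' @return data.frame: ros_uM, sod2 (particles), sod2_rel (fold over the
#'   zero-stress control).
#' @export
run_sod2_dose <- function(ros_levels_uM = c(0, 1, 5, 20, 100),
                          insulin_nM = 2, t_measure = 960,
                          model = build_full_model(), base_state = NULL,
                          config = sim_config()) {
  base <- if (is.null(base_state)) {
    equilibrate_standard(model, config = config)
  } else base_state
  sod2 <- vapply(ros_levels_uM, function(u) {
    s <- base
    s["Ins"] <- insulin_nM_to_particles(insulin_nM)
    s["extracellular_ROS"] <- ros_uM_to_particles(u)
    res <- simulate_model(model, t_measure, init = s,
                          times = seq(0, t_measure, length.out = 25),
                          config = config)
    unname(final_state(res)["Cytoplasm_SOD2"])
  }, numeric(1))
  ref <- sod2[match(0, ros_levels_uM)]
  data.frame(ros_uM = ros_levels_uM, sod2 = sod2,
             sod2_rel = if (length(ref)) sod2 / ref else NA_real_)
}

#' Oxidative-stress preconditioning
#'
#' Phase 1: each initial external ROS level (including 0 = fasting) for
#' `t_phase1` minutes; phase 2: a common moderate stress `phase2_uM` until
#' `t_total`. Tracks total FOXO, DNA-bound FOXO, SOD2, cytoplasmic ROS and
#' total IRS1.
#'
#' @param initial_ros_uM Phase-1 external ROS levels (uM); must include 0.
#' @param insulin_nM Constant insulin (0 or 0.2 in the study design).
#' @param phase2_uM Phase-2 stress (default 20 uM).
#' @param t_phase1 Phase-1 duration (default 1440 min).
#' @param t_total Total duration (default 20000 min).
#' @param model Optional prebuilt model.
#' @param base_state Baseline state (default [equilibrate_standard()]).
#' @param n_out Output points per run.
#' @param config Solver configuration.
#' @return data.frame: precondition_uM, time, total_foxo, dna_foxo, sod2,
#'   cyto_ros, total_irs1.
#' @export
run_preconditioning <- function(initial_ros_uM = c(0, 1, 5, 20, 50),
                                insulin_nM = 0, phase2_uM = 20,
                                t_phase1 = 1440, t_total = 20000,
                                model = build_full_model(),
                                base_state = NULL, n_out = 120,
                                config = sim_config()) {
  stopifnot(0 %in% initial_ros_uM)
  base <- if (is.null(base_state)) {
    equilibrate_standard(model, config = config)
  } else base_state
  base["Ins"] <- insulin_nM_to_particles(insulin_nM)
  foxo_all <- grep("_Foxo1_", names(base), value = TRUE)
  foxo_dna <- grep("^DNAbound_", foxo_all, value = TRUE)
  irs_forms <- c("IRS1", "IRS1_TyrP", "IRS1_PolySerP", "IRS1_TyrP_PolySerP",
                 "IRS1_PI3K")
  out <- lapply(initial_ros_uM, function(u) {
    sched <- schedule(
      time = c(0, t_phase1),
      species = rep("extracellular_ROS", 2),
      amount = c(ros_uM_to_particles(u), ros_uM_to_particles(phase2_uM)))
    res <- simulate_model(model, t_total, sched = sched, init = base,
                          times = seq(0, t_total, length.out = n_out),
                          config = config)
    data.frame(
      precondition_uM = u,
      time = res$times,
      total_foxo = rowSums(res$amounts[, foxo_all, drop = FALSE]),
      dna_foxo = rowSums(res$amounts[, foxo_dna, drop = FALSE]),
      sod2 = res$amounts[, "Cytoplasm_SOD2"],
      cyto_ros = res$amounts[, "cytoplasm_ROS"],
      total_irs1 = rowSums(res$amounts[, irs_forms, drop = FALSE]))
  })
  do.call(rbind, out)
}

#' Diurnal insulin schedule
#'
#' Piecewise-constant emulation of physiological daily insulin variation:
#' a low fasting level with three meal-driven peaks per 1440-min day
#' (breakfast, lunch, dinner), each rising to `amplitude_nM` and relaxing
#' in steps. Deterministic for a fixed seed; `jitter_sd` adds reproducible
#' meal-time jitter.
#'
#' @param days Number of days.
#' @param amplitude_nM Peak insulin (nM); 0 gives a constant schedule.
#' @param basal_nM Fasting insulin (nM).
#' @param period_min Day length (min).
#' @param seed Integer seed for meal-time jitter.
#' @param jitter_sd SD of meal-time jitter (min).
#' @return A [schedule()] for the `Ins` boundary species spanning
#'   `days * period_min` minutes.
#' @export
generate_diurnal_insulin <- function(days = 5, amplitude_nM = 1.2,
                                     basal_nM = 0.2, period_min = 1440,
                                     seed = 1L, jitter_sd = 0) {
  stopifnot(period_min > 0, days >= 1)
  set.seed(seed)
  meal_starts <- period_min * c(0.30, 0.50, 0.75)
  # relative profile of one meal response: rise, peak, stepped decay
  prof_t <- c(0, 15, 45, 90, 150)
  prof_f <- c(1.0, 0.75, 0.4, 0.15, 0)
  times <- 0; amounts <- insulin_nM_to_particles(basal_nM)
  for (d in seq_len(days) - 1) {
    for (ms in meal_starts) {
      jit <- if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
      t0 <- d * period_min + ms + jit
      lv <- basal_nM + (amplitude_nM - basal_nM) * prof_f
      times <- c(times, t0 + prof_t)
      amounts <- c(amounts, insulin_nM_to_particles(lv))
    }
  }
  sched <- schedule(time = times, species = rep("Ins", length(times)),
                    amount = amounts)
  attr(sched, "t_span") <- days * period_min
  sched
}
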