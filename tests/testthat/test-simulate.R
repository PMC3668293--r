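test_that("a model with no reactions stays constant", {
  sp <- species_table(c("A", "B"), "cytoplasm", c(10, 20))
  m <- new_model(sp, list())
  res <- simulate_model(m, 50, times = c(0, 25, 50))
  expect_equal(unname(res$amounts[3, ]), c(10, 20))
})

test_that("first-order decay matches the analytic exponential", {
  sp <- species_table("A", "cytoplasm", 1000)
  m <- new_model(sp, list(
    reaction("dec", reactants = "A",
             law = rate_law("mass_action", list(k = 0.1)))))
  res <- simulate_model(m, 40, times = seq(0, 40, by = 0.5))
  exact <- 1000 * exp(-0.1 * res$times)
  expect_lt(max(abs(res$amounts[, "A"] - exact) / exact), 1e-6)
})

test_that("a scheduled 15-min insulin pulse is reproduced exactly and held between events", {
  model <- signalling_model()
  sched <- schedule(time = c(0, 15),
                    species = c("Ins", "Ins"),
                    amount = c(insulin_nM_to_particles(100), 0))
  res <- simulate_model(model, 30, sched = sched,
                        init = c(extracellular_ROS = 0),
                        times = seq(0, 30, by = 1))
  ins <- res$amounts[, "Ins"]
  expect_true(all(ins[res$times < 15] == insulin_nM_to_particles(100)))
  expect_true(all(ins[res$times > 15] == 0))
})

test_that("schedules only address boundary species", {
  model <- signalling_model()
  bad <- schedule(time = 5, species = "Akt", amount = 0)
  expect_error(simulate_model(model, 10, sched = bad),
               "non-boundary species")
})

test_that("integrating across an event equals splitting the run at the event", {
  model <- signalling_model()
  sched <- schedule(time = 10, species = "Ins",
                    amount = insulin_nM_to_particles(10))
  whole <- simulate_model(model, 20, sched = sched,
                          init = c(Ins = 0, extracellular_ROS = 0),
                          times = c(0, 10, 20))
  part1 <- simulate_model(model, 10,
                          init = c(Ins = 0, extracellular_ROS = 0),
                          times = c(0, 10))
  s_mid <- final_state(part1)
  s_mid["Ins"] <- insulin_nM_to_particles(10)
  part2 <- simulate_model(model, 10, init = s_mid, times = c(0, 10))
  expect_equal(unname(final_state(whole)), unname(final_state(part2)),
               tolerance = 1e-6)
})

test_that("no species goes below the solver tolerance under stimulation", {
  model <- full_model()
  res <- simulate_model(model, 120,
                        init = c(Ins = insulin_nM_to_particles(100),
                                 extracellular_ROS = ros_uM_to_particles(5)),
                        times = seq(0, 120, by = 2))
  expect_gt(min(res$amounts), -1e-3)
})

test_that("halving the solver tolerances leaves readouts essentially unchanged", {
  model <- signalling_model()
  run <- function(cfg) {
    res <- simulate_model(model, 30,
                          init = c(Ins = insulin_nM_to_particles(100),
                                   extracellular_ROS = 0),
                          times = c(0, 15, 30), config = cfg)
    readout_fractions(final_state(res))
  }
  a <- run(sim_config())
  b <- run(sim_config(rtol = 5e-9, atol = 5e-7))
  keep <- !is.na(a)
  expect_lt(max(abs(a[keep] - b[keep]) / pmax(abs(a[keep]), 1e-6)), 1e-3)
})

test_that("identical configurations reproduce bit-identical trajectories", {
  model <- signalling_model()
  r1 <- simulate_model(model, 20, init = c(Ins = 1000),
                       times = seq(0, 20, by = 1))
  r2 <- simulate_model(model, 20, init = c(Ins = 1000),
                       times = seq(0, 20, by = 1))
  expect_identical(r1$amounts, r2$amounts)
})
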