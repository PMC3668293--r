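test_that("FOXO state space is 16 PTM combinations x 3 compartments", {
  st <- foxo_states()
  expect_equal(nrow(st), 48)
  expect_equal(sum(st$compartment == "cytoplasm"), 16)
  expect_false(anyDuplicated(st$name) > 0)
  sp <- enumerate_foxo_species()
  expect_equal(nrow(sp), 48)
  expect_equal(sp$amount[sp$name == "cytoplasm_Foxo1_Pa0_Pd0_Pe0_pUb0"],
               1000)
  expect_equal(sum(sp$amount), 1000)  # all other states start empty
})

test_that("PTM rate modifiers combine multiplicatively", {
  tab <- default_foxo_modifiers()
  st0 <- list(Pa = 0, Pd = 0, Pe = 0, pUb = 0)
  expect_equal(foxo_effective_rate("cyt_to_nuc", st0, tab), 0.182)
  expect_equal(foxo_effective_rate("cyt_to_nuc",
                                   list(Pa = 1, Pd = 0, Pe = 0, pUb = 0),
                                   tab), 0.0182)
  # Pa and Pe modifiers cancel: 0.182 * 0.1 * 10
  expect_equal(foxo_effective_rate("cyt_to_nuc",
                                   list(Pa = 1, Pd = 0, Pe = 1, pUb = 0),
                                   tab), 0.182)
  # ubiquitination: base 1e-6, Pa x3, Pd x22
  expect_equal(foxo_effective_rate("ubiquitination", st0, tab), 1e-6)
  expect_equal(foxo_effective_rate("ubiquitination",
                                   list(Pa = 1, Pd = 1, Pe = 0, pUb = 0),
                                   tab), 1e-6 * 3 * 22)
  expect_error(foxo_effective_rate("acetylation", st0, tab),
               "unknown FOXO process")
})

test_that("generated ubiquitination fluxes reproduce the printed worked rates", {
  model <- full_model()
  ids <- vapply(model$reactions, function(r) r$id, character(1))
  state <- stats::setNames(rep(0, nrow(model$species)), model$species$name)
  state["SCF_MDM2"] <- 1000
  # base ubiquitination of the unmodified cytoplasmic state: 1e-6 * 1000
  # per FOXO per minute
  state["cytoplasm_Foxo1_Pa0_Pd0_Pe0_pUb0"] <- 1
  r <- model$reactions[[which(ids == "Foxo_ub_Pa0_Pd0_Pe0_pUb0")]]
  expect_equal(evaluate_rate(r, state), 1e-3)
  # Pa + Pd state: 1e-3 * 3 * 22 per molecule
  state2 <- state
  state2["cytoplasm_Foxo1_Pa0_Pd0_Pe0_pUb0"] <- 0
  state2["cytoplasm_Foxo1_Pa1_Pd1_Pe0_pUb0"] <- 1
  r2 <- model$reactions[[which(ids == "Foxo_ub_Pa1_Pd1_Pe0_pUb0")]]
  expect_equal(evaluate_rate(r2, state2), 6.6e-2)
})

test_that("reaction census matches an independent combinatorial count", {
  rx <- generate_foxo_reactions()
  # independent count over (compartment, PTM) states and applicable
  # processes: 1 synthesis; transport cyt<->nuc 2*16 and nuc<->DNA 2*16;
  # for each of cytoplasm and nucleus, each of 3 marks is either addable or
  # removable (16 states each); ubiquitination for cytoplasmic pUb0 (8) and
  # degradation for cytoplasmic pUb1 (8)
  n_expected <- 1 + 2 * 16 + 2 * 16 + 2 * 3 * 16 + 8 + 8
  expect_equal(length(rx), n_expected)
  ids <- vapply(rx, function(r) r$id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  # no kinase marks are applied in the DNA-bound compartment
  expect_false(any(grepl("Foxo_DNAbound_", ids)))
})

test_that("only ubiquitinated cytoplasmic FOXO is degraded", {
  rx <- generate_foxo_reactions()
  deg <- Filter(function(r) length(r$products) == 0 &&
                  grepl("Foxo1", r$reactants[1]), rx)
  expect_equal(length(deg), 8)
  expect_true(all(grepl("^cytoplasm_.*pUb1$",
                        vapply(deg, function(r) r$reactants[1],
                               character(1)))))
})

test_that("insulin drives FOXO cytoplasmic, stress drives it nuclear", {
  model <- full_model()
  foxo <- grep("_Foxo1_", model$species$name, value = TRUE)
  nuc_dna <- grep("^(nucleus|DNAbound)_", foxo, value = TRUE)
  loc_frac <- function(state) {
    sum(state[nuc_dna]) / sum(state[foxo])
  }
  # high insulin, 12 h
  hi_ins <- simulate_model(model, 720,
                           init = c(Ins = insulin_nM_to_particles(100),
                                    extracellular_ROS = 0),
                           times = c(0, 360, 720))
  # no insulin, strong external oxidant (JNK active, IKK lagging)
  hi_ros <- simulate_model(model, 720,
                           init = c(Ins = 0,
                                    extracellular_ROS =
                                      ros_uM_to_particles(20)),
                           times = c(0, 360, 720))
  f_ins <- loc_frac(final_state(hi_ins))
  f_ros <- loc_frac(final_state(hi_ros))
  expect_lt(f_ins, 0.5)   # predominantly cytoplasmic under insulin
  expect_gt(f_ros, f_ins) # stress shifts FOXO toward nucleus/DNA
})
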