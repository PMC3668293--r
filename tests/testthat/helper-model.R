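# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

full_model <- function() cached("full_model", build_full_model())

signalling_model <- function() {
  cached("signalling_model",
         build_full_model(foxo = FALSE, transcription = FALSE))
}

# basal state of the full model (insulin 0, no external oxidant), signalling
# layer relaxed
basal_state <- function() {
  cached("basal_state", {
    res <- simulate_model(full_model(), 720,
                          init = c(Ins = 0, extracellular_ROS = 0),
                          times = c(0, 360, 720))
    final_state(res)
  })
}

# fed baseline from the two-stage equilibration recipe (diurnal + 0.2 nM)
equilibrated_state <- function() {
  cached("equilibrated_state", equilibrate_standard(full_model()))
}

# a minimal reversible pair A <-> B for solver-level tests
toy_pair_model <- function(kf = 0.2, kr = 0.1, a0 = 300, b0 = 600) {
  sp <- species_table(name = c("A", "B"), compartment = "cytoplasm",
                      amount = c(a0, b0))
  new_model(sp, list(
    reaction("fwd", reactants = "A", products = "B",
             law = rate_law("mass_action", list(k = kf))),
    reaction("rev", reactants = "B", products = "A",
             law = rate_law("mass_action", list(k = kr)))))
}

random_state <- function(model, seed) {
  set.seed(seed)
  stats::setNames(stats::runif(nrow(model$species), 0, 1e5),
                  model$species$name)
}
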