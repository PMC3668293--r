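test_that("receptor module carries the 14 printed rate entries and core species", {
  mod <- build_module("receptor")
  expect_setequal(
    vapply(mod$reactions, function(r) r$id, character(1)),
    c("R1f", "R1r", "R2", "R3f", "R3r", "R4", "R5f", "R5r",
      "R6f", "R6r", "R7f", "R7r", "R10", "R11"))
  expect_true(all(c("Ins", "InR", "cytoplasm_InR", "PTP1B") %in%
                    mod$species$name))
  expect_true(mod$species$boundary[mod$species$name == "Ins"])
})

test_that("phosphatase module contains the NOX cycle, ROS turnover, transport and GSH redox", {
  mod <- build_module("phosphatases")
  ids <- vapply(mod$reactions, function(r) r$id, character(1))
  expect_true(all(c("R34f", "R34r1", "R34r2", "R34r3",
                    "R35f", "R35r", "R36f",
                    "R37f", "R37r", "R38f", "R38r") %in% ids))
  expect_true(all(c("R30f", "R30r", "R31f", "R31r") %in% ids))
})

test_that("unknown module names are rejected", {
  expect_error(build_module("glycolysis"), "unknown module")
})

test_that("module reactions carry exactly the printed constants", {
  p <- default_parameters()
  mod <- build_module("irs")
  rx <- mod$reactions[[which(vapply(mod$reactions, function(r) r$id,
                                    character(1)) == "R13f")]]
  expect_equal(rx$law$constants$k, 2.6e-6)
  rx51 <- mod$reactions[[which(vapply(mod$reactions, function(r) r$id,
                                      character(1)) == "R51_a")]]
  expect_equal(rx51$law$constants$kcat, 0.87)
  expect_equal(rx51$law$constants$Km, 100)
  # Ser-phosphorylated IRS degrades 10x faster than the base forms
  expect_equal(p$irs$R50r3[["k"]] / p$irs$R50r1[["k"]], 10)
})

test_that("merging keeps the first declaration of a shared species", {
  recep <- build_module("receptor")
  phos <- build_module("phosphatases")
  # both declare PTP1B; tag the first one's initial value
  recep$species$amount[recep$species$name == "PTP1B"] <- 1234
  m <- merge_modules(list(recep, phos))
  expect_equal(sum(m$species$name == "PTP1B"), 1)
  expect_equal(m$species$amount[m$species$name == "PTP1B"], 1234)
})

test_that("merging disjoint parts sums the species counts", {
  a <- list(species = species_table("X1", "cytoplasm", 1),
            reactions = list())
  b <- list(species = species_table(c("X2", "X3"), "cytoplasm", c(1, 2)),
            reactions = list())
  m <- merge_modules(list(a, b))
  expect_equal(nrow(m$species), 3)
})

test_that("conflicting compartment assignment for a shared species is an error", {
  a <- list(species = species_table("X", "cytoplasm", 1), reactions = list())
  b <- list(species = species_table("X", "nucleus", 1), reactions = list())
  expect_error(merge_modules(list(a, b)), "conflicting compartment")
})

test_that("the full merged model covers every printed initial-condition row", {
  model <- full_model()
  printed <- c(
    Ins = 5e5, InR = 9e4, cytoplasm_InR = 1e4, PTP1B = 1e5,
    IRS1 = 1e5, PI3K = 1e4, PP2A = 5e5,
    PTEN = 1e5, GSH = 100, NOX_inact = 100, Cytoplasm_SOD2 = 4.17e4,
    Mt = 50, extracellular_ROS = 5e4,
    Akt = 1e5, AS160 = 2e4, PKC = 1e5, PIP2 = 2e5, PIP3 = 1e3,
    cytoplasm_GLUT4 = 9.6e4, cellsurface_GLUT4 = 4e3,
    JNK = 16000, IKK = 2000, DUSP = 1e5, E2F1 = 300,
    cytoplasm_Foxo1_Pa0_Pd0_Pe0_pUb0 = 1000)
  expect_true(all(names(printed) %in% model$species$name))
  got <- stats::setNames(model$species$amount, model$species$name)
  expect_equal(unname(got[names(printed)]), unname(printed))
  # scaled species carry the 1000x representation factor
  scl <- stats::setNames(model$species$scale, model$species$name)
  expect_equal(unname(scl[c("cytoplasm_ROS", "extracellular_ROS",
                            "Cytoplasm_SOD2", "PIP2", "PIP3")]),
               rep(1000, 5))
})

test_that("IRS state space is exactly the four printed phospho-forms", {
  mod <- build_module("irs")
  irs <- grep("^IRS1", mod$species$name, value = TRUE)
  expect_setequal(irs, c("IRS1", "IRS1_TyrP", "IRS1_PolySerP",
                         "IRS1_TyrP_PolySerP", "IRS1_PI3K"))
})
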