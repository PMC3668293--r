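test_that("fold change depends only on DNA-bound FOXO and the two transcription rates", {
  gp <- default_gene_params()
  expect_equal(fold_change(gp$InR, 0), 1.0)
  expect_equal(fold_change(gp$InR, 21), (5.0 + 0.24 * 21) / 5.0)
  expect_equal(fold_change(gp$SOD2, 16), (15.0 + 0.95 * 16) / 15.0)
  expect_error(fold_change(c(gp$InR[-2], k_basalt = 0), 1), "k_basalt")
  expect_error(fold_change(gp$InR, -1), "F must be >= 0")
})

test_that("printed per-gene constants are wired into the reactions", {
  g <- build_gene("InR")
  ids <- vapply(g$reactions, function(r) r$id, character(1))
  pdeg <- g$reactions[[which(ids == "InR_pdeg")]]
  expect_equal(pdeg$law$constants$k, 4.4e-3)
  txn <- g$reactions[[which(ids == "InR_txn")]]
  expect_equal(txn$law$constants$k_basal, 5.0)
  expect_equal(txn$law$constants$k_stim, 0.24)
  expect_equal(length(txn$modifiers), 16)  # all DNA-bound FOXO states
  expect_error(build_gene("PDK4"), "unknown gene")
})

# linear chain: mRNA_nuc -> mRNA_cyt -> protein with fixed DNA-bound FOXO F
.gene_chain_model <- function(gene, F_fixed) {
  dna <- "DNA_FOXO_fixed"
  part <- build_gene(gene, foxo_readout = dna)
  sp <- rbind(part$species,
              species_table(dna, "DNAbound", F_fixed, boundary = TRUE))
  class(sp) <- c("insox_species", "data.frame")
  new_model(sp, part$reactions)
}

test_that("long-time integration reaches the closed-form steady state of the expression chain", {
  for (F_fixed in c(0, 30)) {
    m <- .gene_chain_model("SOD2", F_fixed)
    p <- as.list(default_gene_params()$SOD2)
    res <- simulate_model(m, 20000, times = c(0, 10000, 20000))
    fin <- final_state(res)
    txn <- p$k_basalt + p$k_foxot * F_fixed
    expect_equal(fin[["SOD2_mRNA_nuc"]], txn / p$k_exp, tolerance = 1e-5)
    expect_equal(fin[["SOD2_mRNA_cyt"]], txn / p$k_mdeg, tolerance = 1e-5)
    expect_equal(fin[["Cytoplasm_SOD2"]],
                 p$k_transl * txn / (p$k_mdeg * p$k_pdeg), tolerance = 1e-4)
  }
})

test_that("fold change is invariant to 10x perturbations of the non-transcription constants", {
  base <- default_gene_params()$InR
  F_on <- 25
  steady_protein <- function(pars, F) {
    p <- as.list(pars)
    p$k_transl * (p$k_basalt + p$k_foxot * F) / (p$k_mdeg * p$k_pdeg)
  }
  ratio0 <- steady_protein(base, F_on) / steady_protein(base, 0)
  for (nm in c("k_exp", "k_mdeg", "k_transl", "k_pdeg")) {
    pert <- base
    pert[nm] <- pert[nm] * 10
    # verify numerically against the integrated chain, not just the formula
    m_on <- .gene_chain_model("InR", F_on)
    m_off <- .gene_chain_model("InR", 0)
    ids <- vapply(m_on$reactions, function(r) r$id, character(1))
    override <- function(m) {
      m$reactions <- lapply(m$reactions, function(r) {
        if (r$id == "InR_exp" && nm == "k_exp") r$law$constants$k <- pert[[nm]]
        if (r$id == "InR_mdeg" && nm == "k_mdeg") r$law$constants$k <- pert[[nm]]
        if (r$id == "InR_transl" && nm == "k_transl") r$law$constants$k <- pert[[nm]]
        if (r$id == "InR_pdeg" && nm == "k_pdeg") r$law$constants$k <- pert[[nm]]
        r
      })
      m
    }
    fin_on <- final_state(simulate_model(override(m_on), 60000,
                                         times = c(0, 30000, 60000)))
    fin_off <- final_state(simulate_model(override(m_off), 60000,
                                          times = c(0, 30000, 60000)))
    ratio <- fin_on[["InR"]] / fin_off[["InR"]]
    expect_equal(ratio, ratio0, tolerance = 1e-4)
    expect_equal(ratio, fold_change(base, F_on), tolerance = 1e-4)
  }
})

test_that("mRNA responds to a FOXO step much faster than protein", {
  m <- .gene_chain_model("InR", 0)
  # settle at F = 0, then step F via the boundary species
  s0 <- final_state(simulate_model(m, 5000, times = c(0, 5000)))
  s0["DNA_FOXO_fixed"] <- 40
  res <- simulate_model(m, 2000, init = s0,
                        times = seq(0, 2000, by = 1))
  t90 <- function(x) {
    target <- x[1] + 0.9 * (x[length(x)] - x[1])
    res$times[which(x >= target)[1]]
  }
  t90_mrna <- t90(res$amounts[, "InR_mRNA_cyt"])
  t90_prot <- t90(res$amounts[, "InR"])
  expect_lt(t90_mrna, 30)        # tens of minutes
  expect_gt(t90_prot, 5 * t90_mrna)
})
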