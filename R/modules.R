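#' Default kinetic parameters of the signalling modules
#'
#' Nested list: module -> reaction id -> named constants, in per-particle,
#' per-minute units. These are the printed rate constants of the model's
#' five non-FOXO modules. One documented exception to the per-particle
#' convention: `k7` (IRS1 Tyr phosphorylation by the activated receptor) is
#' normalized by the total receptor number (1e5), following the receptor-
#' fraction convention of the lineage model this pathway derives from; the
#' per-particle reading would phosphorylate the whole IRS1 pool within
#' seconds at any insulin dose.
#'
#' @return Nested named list of constants.
#' @export
default_parameters <- function() {
  list(
    receptor = list(
      R1f = c(k = 2.0e-5), R1r = c(k = 12072), R2 = c(k = 2500),
      R3f = c(k = 1.2e-5), R3r = c(k = 9e4), R4 = c(k = 2e-6),
      R5f = c(k = 0.0333), R5r = c(k = 0.3),
      R6f = c(k = 0.0021), R6r = c(k = 2.1e-4),
      R7f = c(k = 0.0021), R7r = c(k = 2.1e-4),
      R10 = c(k = 4.61e-6), R11 = c(k = 4.61e-6)),
    irs = list(
      R12f = c(k = 5.8 / 1e5), R12r = c(k = 8.75e-5),
      R12_a_f = c(k = 2.2e-4), R12_a_r = c(k = 2.8e-6),
      R12_b_f = c(k = 2.2e-4), R12_b_r = c(k = 2.8e-6),
      R13f = c(k = 2.6e-6), R13r = c(k = 1.55),
      R50f = c(k = 260),
      R50r1 = c(k = 1e-3), R50r2 = c(k = 1e-3),
      R50r3 = c(k = 1e-2), R50r4 = c(k = 1e-2),
      R51_a = c(kcat = 0.87, Km = 100), R51_b = c(kcat = 0.87, Km = 100),
      R52_a = c(kcat = 6.95, Km = 100), R52_b = c(kcat = 6.95, Km = 100)),
    akt = list(
      R14f_basal = c(k = 0.13145), R14f_cat = c(k = 0.055),
      R14r_basal = c(k = 2.7), R14r_cat = c(k = 0.0014),
      R16f = c(k = 2.5e-5, offset = 200), R16r = c(k = 1.188e-6),
      R17f = c(k = 3.5e-5, offset = 200), R17r = c(k = 1.25e-6),
      R16a_f = c(k = 3.33e-4), R16a_r = c(k = 1e-6),
      R20f_basal = c(k = 0.015), R20f_cat = c(k = 7.5e-6),
      R20r = c(k = 0.167)),
    phosphatases = list(
      R30f = c(k = 0.08), R30r = c(k = 5e-3),
      R31f = c(k = 2.7e-4), R31r = c(k = 2e-3),
      R34f = c(k = 2e-5), R34r1 = c(k = 1e-3), R34r2 = c(k = 0.25),
      R34r3 = c(k = 1e-3),
      R35f = c(k = 450), R35r = c(k = 0.12), R36f = c(k = 180),
      R37f = c(k = 4.8), R37r = c(k = 4.8),
      R38f = c(k = 0.05), R38r = c(k = 2)),
    jnk = list(
      R32f = c(k = 6e-4), R32r = c(k = 4e-4),
      R42f = c(k = 2.5e-4), R42r = c(k = 0.5e-6),
      R43f = c(k = 0.5e-4), R43r = c(k = 0.5e-6))
  )
}

#' Initial particle numbers of the signalling species
#'
#' @return Named numeric vector of initial amounts.
#' @export
default_initial_amounts <- function() {
  c(Ins = 5e5, InR = 9e4, InR_Ins = 0, InR_Ins_P = 0, InR_Ins2_P = 0,
    cytoplasm_InR = 1e4, cytoplasm_InR_Ins_P = 0, cytoplasm_InR_Ins2_P = 0,
    PTP1B = 1e5, PTP1B_ox = 0,
    IRS1 = 1e5, IRS1_TyrP = 0, IRS1_PolySerP = 0, IRS1_TyrP_PolySerP = 0,
    PI3K = 1e4, IRS1_PI3K = 0, PP2A = 5e5,
    PTEN = 1e5, PTEN_ox = 0, GSH = 100, GSH_ox = 0,
    NOX_inact = 100, NOX_act = 0, NOX_deact = 0,
    Cytoplasm_SOD2 = 4.17e4, Mt = 50,
    extracellular_ROS = 5e4, cytoplasm_ROS = 0,
    Akt = 1e5, Akt_P = 0, AS160 = 2e4, AS160_P = 0,
    PKC = 1e5, PKC_P = 0, PIP2 = 2e5, PIP3 = 1e3,
    cytoplasm_GLUT4 = 9.6e4, cellsurface_GLUT4 = 4e3,
    JNK = 16000, JNK_P = 0, IKK = 2000, IKK_P = 0,
    DUSP = 1e5, DUSP_ox = 0)
}

# compartment, boundary and scale annotations for the signalling species
.species_meta <- function() {
  surf <- c("InR", "InR_Ins", "InR_Ins_P", "InR_Ins2_P", "cellsurface_GLUT4")
  extr <- c("Ins", "extracellular_ROS")
  list(
    compartment = function(nm) {
      ifelse(nm %in% extr, "extracellular",
             ifelse(nm %in% surf, "cellsurface", "cytoplasm"))
    },
    boundary = c("Ins", "extracellular_ROS"),
    scaled = c("cytoplasm_ROS", "extracellular_ROS", "Cytoplasm_SOD2",
               "PIP2", "PIP3"))
}

.make_species <- function(names, amounts = default_initial_amounts()) {
  meta <- .species_meta()
  species_table(
    name = names,
    compartment = meta$compartment(names),
    amount = unname(amounts[names]),
    boundary = names %in% meta$boundary,
    scale = ifelse(names %in% meta$scaled, 1000, 1))
}

.ma <- function(id, from, to, k, modifiers = character()) {
  kind <- if (length(modifiers)) "catalytic" else "mass_action"
  reaction(id, reactants = from, products = to, modifiers = modifiers,
           law = rate_law(kind, list(k = k)))
}

#' Build one of the five signalling sub-networks
#'
#' Constructs the species and reactions of a named module: `receptor`
#' (insulin binding, receptor activation, internalization/recycling), `irs`
#' (IRS1 Tyr/Ser phosphorylation states, PI3K complex, turnover), `akt`
#' (PIP3, Akt/PKC activation with the basal-PIP3 offset, AS160 and GLUT4
#' translocation), `phosphatases` (PTP1B/PTEN redox, NOX cycle, ROS
#' production/elimination/transport, glutathione) or `jnk` (DUSP redox and
#' ROS-driven JNK/IKK activation).
#'
#' Modules declare every species they reference (including shared pools such
#' as PTP1B or PP2A) so each is a standalone network; [merge_modules()]
#' resolves duplicates keeping the first declaration.
#'
#' @param name Module name.
#' @param params Parameter set as from [default_parameters()].
#' @param amounts Initial amounts as from [default_initial_amounts()].
#' @return List with elements `species` and `reactions`.
#' @export
build_module <- function(name, params = default_parameters(),
                         amounts = default_initial_amounts()) {
  if (!name %in% names(params)) {
    stop("unknown module name: ", name, call. = FALSE)
  }
  p <- params[[name]]
  k <- function(id) unname(p[[id]]["k"])
  out <- switch(name,
    receptor = {
      spn <- c("Ins", "InR", "InR_Ins", "InR_Ins_P", "InR_Ins2_P",
               "cytoplasm_InR", "cytoplasm_InR_Ins_P",
               "cytoplasm_InR_Ins2_P", "PTP1B")
      rx <- list(
        .ma("R1f", c("Ins", "InR"), "InR_Ins", k("R1f")),
        .ma("R1r", "InR_Ins", c("Ins", "InR"), k("R1r")),
        .ma("R2", "InR_Ins", "InR_Ins_P", k("R2")),
        .ma("R3f", c("Ins", "InR_Ins_P"), "InR_Ins2_P", k("R3f")),
        .ma("R3r", "InR_Ins2_P", c("Ins", "InR_Ins_P"), k("R3r")),
        .ma("R4", "InR_Ins_P", c("InR", "Ins"), k("R4"), "PTP1B"),
        .ma("R5f", "InR", "cytoplasm_InR", k("R5f")),
        .ma("R5r", "cytoplasm_InR", "InR", k("R5r")),
        .ma("R6f", "InR_Ins_P", "cytoplasm_InR_Ins_P", k("R6f")),
        .ma("R6r", "cytoplasm_InR_Ins_P", "InR_Ins_P", k("R6r")),
        .ma("R7f", "InR_Ins2_P", "cytoplasm_InR_Ins2_P", k("R7f")),
        .ma("R7r", "cytoplasm_InR_Ins2_P", "InR_Ins2_P", k("R7r")),
        .ma("R10", "cytoplasm_InR_Ins_P", c("cytoplasm_InR", "Ins"),
            k("R10"), "PTP1B"),
        .ma("R11", "cytoplasm_InR_Ins2_P", c("cytoplasm_InR", "Ins"),
            k("R11"), "PTP1B"))
      list(species = spn, reactions = rx)
    },
    irs = {
      spn <- c("IRS1", "IRS1_TyrP", "IRS1_PolySerP", "IRS1_TyrP_PolySerP",
               "PI3K", "IRS1_PI3K", "PP2A", "PTP1B", "PKC_P",
               "InR_Ins_P", "InR_Ins2_P", "IKK_P", "JNK_P")
      mm <- function(id, from, to, enz) {
        reaction(id, reactants = from, products = to, modifiers = enz,
                 law = rate_law("michaelis_menten",
                                list(kcat = unname(p[[id]]["kcat"]),
                                     Km = unname(p[[id]]["Km"]))))
      }
      rx <- list(
        .ma("R12f", "IRS1", "IRS1_TyrP", k("R12f"),
            c("InR_Ins_P", "InR_Ins2_P")),
        .ma("R12r", "IRS1_TyrP", "IRS1", k("R12r"), "PTP1B"),
        .ma("R12_a_f", "IRS1", "IRS1_PolySerP", k("R12_a_f"), "PKC_P"),
        .ma("R12_a_r", "IRS1_PolySerP", "IRS1", k("R12_a_r"), "PP2A"),
        .ma("R12_b_f", "IRS1_TyrP", "IRS1_TyrP_PolySerP", k("R12_b_f"),
            "PKC_P"),
        .ma("R12_b_r", "IRS1_TyrP_PolySerP", "IRS1_TyrP", k("R12_b_r"),
            "PP2A"),
        .ma("R13f", c("IRS1_TyrP", "PI3K"), "IRS1_PI3K", k("R13f")),
        .ma("R13r", "IRS1_PI3K", c("IRS1_TyrP", "PI3K"), k("R13r")),
        reaction("R50f", products = "IRS1",
                 law = rate_law("zero_order", list(k = k("R50f")))),
        .ma("R50r1", "IRS1", character(), k("R50r1")),
        .ma("R50r2", "IRS1_TyrP", character(), k("R50r2")),
        .ma("R50r3", "IRS1_PolySerP", character(), k("R50r3")),
        .ma("R50r4", "IRS1_TyrP_PolySerP", character(), k("R50r4")),
        mm("R51_a", "IRS1", "IRS1_PolySerP", "IKK_P"),
        mm("R51_b", "IRS1_TyrP", "IRS1_TyrP_PolySerP", "IKK_P"),
        mm("R52_a", "IRS1", "IRS1_PolySerP", "JNK_P"),
        mm("R52_b", "IRS1_TyrP", "IRS1_TyrP_PolySerP", "JNK_P"))
      list(species = spn, reactions = rx)
    },
    akt = {
      spn <- c("PIP2", "PIP3", "IRS1_PI3K", "PTEN", "Akt", "Akt_P",
               "PKC", "PKC_P", "AS160", "AS160_P", "PP2A",
               "cytoplasm_GLUT4", "cellsurface_GLUT4")
      off <- function(id, from, to) {
        reaction(id, reactants = from, products = to, modifiers = "PIP3",
                 law = rate_law("offset_mass_action",
                                list(k = unname(p[[id]]["k"]),
                                     offset = unname(p[[id]]["offset"]))))
      }
      rx <- list(
        .ma("R14f_basal", "PIP2", "PIP3", k("R14f_basal")),
        .ma("R14f_cat", "PIP2", "PIP3", k("R14f_cat"), "IRS1_PI3K"),
        .ma("R14r_basal", "PIP3", "PIP2", k("R14r_basal")),
        .ma("R14r_cat", "PIP3", "PIP2", k("R14r_cat"), "PTEN"),
        off("R16f", "Akt", "Akt_P"),
        .ma("R16r", "Akt_P", "Akt", k("R16r"), "PP2A"),
        off("R17f", "PKC", "PKC_P"),
        .ma("R17r", "PKC_P", "PKC", k("R17r"), "PP2A"),
        .ma("R16a_f", "AS160", "AS160_P", k("R16a_f"), "Akt_P"),
        .ma("R16a_r", "AS160_P", "AS160", k("R16a_r"), "PP2A"),
        .ma("R20f_basal", "cytoplasm_GLUT4", "cellsurface_GLUT4",
            k("R20f_basal")),
        .ma("R20f_cat", "cytoplasm_GLUT4", "cellsurface_GLUT4",
            k("R20f_cat"), "AS160_P"),
        .ma("R20r", "cellsurface_GLUT4", "cytoplasm_GLUT4", k("R20r")))
      list(species = spn, reactions = rx)
    },
    phosphatases = {
      spn <- c("PTP1B", "PTP1B_ox", "PTEN", "PTEN_ox", "GSH", "GSH_ox",
               "NOX_inact", "NOX_act", "NOX_deact", "Cytoplasm_SOD2", "Mt",
               "extracellular_ROS", "cytoplasm_ROS", "Ins")
      rx <- list(
        .ma("R30f", "PTP1B", "PTP1B_ox", k("R30f"), "cytoplasm_ROS"),
        .ma("R30r", "PTP1B_ox", "PTP1B", k("R30r"), "GSH"),
        .ma("R31f", "PTEN", "PTEN_ox", k("R31f"), "cytoplasm_ROS"),
        .ma("R31r", "PTEN_ox", "PTEN", k("R31r"), "GSH"),
        .ma("R34f", "NOX_inact", "NOX_act", k("R34f"), "Ins"),
        .ma("R34r2", "NOX_act", "NOX_deact", k("R34r2")),
        .ma("R34r1", "NOX_deact", "NOX_inact", k("R34r1")),
        .ma("R34r3", "NOX_act", "NOX_inact", k("R34r3")),
        reaction("R35f", products = "cytoplasm_ROS", modifiers = "NOX_act",
                 law = rate_law("synthesis", list(k = k("R35f")))),
        .ma("R35r", "cytoplasm_ROS", character(), k("R35r"),
            "Cytoplasm_SOD2"),
        reaction("R36f", products = "cytoplasm_ROS", modifiers = "Mt",
                 law = rate_law("synthesis", list(k = k("R36f")))),
        .ma("R37f", "extracellular_ROS", "cytoplasm_ROS", k("R37f")),
        .ma("R37r", "cytoplasm_ROS", "extracellular_ROS", k("R37r")),
        .ma("R38f", "GSH", "GSH_ox", k("R38f"), "cytoplasm_ROS"),
        .ma("R38r", "GSH_ox", "GSH", k("R38r")))
      list(species = spn, reactions = rx)
    },
    jnk = {
      spn <- c("DUSP", "DUSP_ox", "JNK", "JNK_P", "IKK", "IKK_P",
               "GSH", "cytoplasm_ROS")
      rx <- list(
        .ma("R32f", "DUSP", "DUSP_ox", k("R32f"), "cytoplasm_ROS"),
        .ma("R32r", "DUSP_ox", "DUSP", k("R32r"), "GSH"),
        .ma("R42f", "JNK", "JNK_P", k("R42f"), "cytoplasm_ROS"),
        .ma("R42r", "JNK_P", "JNK", k("R42r"), "DUSP"),
        .ma("R43f", "IKK", "IKK_P", k("R43f"), "cytoplasm_ROS"),
        .ma("R43r", "IKK_P", "IKK", k("R43r"), "DUSP"))
      list(species = spn, reactions = rx)
    })
  list(species = .make_species(out$species, amounts),
       reactions = out$reactions)
}

#' Merge module networks into one model
#'
#' Duplicate species declarations are resolved keeping the first occurrence
#' (the merge convention of the source pipeline); reaction ids must be
#' unique. Declaring the same species in different compartments is an error.
#'
#' @param parts List of module parts, each a list with `species` and
#'   `reactions`.
#' @param compartments Compartment table.
#' @return An [new_model()] object.
#' @export
merge_modules <- function(parts, compartments = default_compartments()) {
  all_sp <- do.call(rbind, lapply(parts, function(p) p$species))
  first <- !duplicated(all_sp$name)
  dup <- all_sp[!first, , drop = FALSE]
  kept <- all_sp[first, , drop = FALSE]
  if (nrow(dup)) {
    comp_of <- stats::setNames(kept$compartment, kept$name)
    clash <- dup$compartment != comp_of[dup$name]
    if (any(clash)) {
      stop("conflicting compartment assignment for species: ",
           paste(unique(dup$name[clash]), collapse = ", "), call. = FALSE)
    }
  }
  class(kept) <- c("insox_species", "data.frame")
  rownames(kept) <- NULL
  rxns <- do.call(c, lapply(parts, function(p) p$reactions))
  new_model(kept, rxns, compartments)
}

#' Assemble the full signalling + FOXO + transcription model
#'
#' Merges the five signalling modules, the rule-generated FOXO module and
#' the InR/SOD2 transcription units into one network.
#'
#' @param params Signalling parameters ([default_parameters()]).
#' @param amounts Initial amounts ([default_initial_amounts()]).
#' @param foxo Include the FOXO module (default TRUE).
#' @param transcription Include FOXO-driven InR/SOD2 expression (requires
#'   `foxo`; default TRUE).
#' @param modifier_table FOXO rate-modifier table
#'   ([default_foxo_modifiers()]).
#' @param gene_params Transcription parameters ([default_gene_params()]).
#' @return An [new_model()] object.
#' @export
build_full_model <- function(params = default_parameters(),
                             amounts = default_initial_amounts(),
                             foxo = TRUE, transcription = TRUE,
                             modifier_table = default_foxo_modifiers(),
                             gene_params = default_gene_params()) {
  parts <- lapply(c("receptor", "irs", "akt", "phosphatases", "jnk"),
                  build_module, params = params, amounts = amounts)
  if (foxo) {
    parts <- c(parts, list(build_foxo_module(modifier_table)))
  }
  if (transcription) {
    if (!foxo) stop("transcription requires the FOXO module", call. = FALSE)
    parts <- c(parts,
               list(build_gene("InR", gene_params[["InR"]]),
                    build_gene("SOD2", gene_params[["SOD2"]])))
  }
  merge_modules(parts)
}
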