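#' FOXO state helpers
#'
#' FOXO1 carries four binary post-translational marks — Pa (Akt phospho),
#' Pd (IKK phospho), Pe (JNK phospho), pUb (ubiquitin) — and lives in one of
#' three compartments (cytoplasm, nucleus, DNA-bound). Species names encode
#' the state, e.g. `cytoplasm_Foxo1_Pa0_Pd0_Pe0_pUb0`.
#'
#' @param compartment One of "cytoplasm", "nucleus", "DNAbound".
#' @param Pa,Pd,Pe,pUb 0/1 flags.
#' @return Species name string.
#' @export
foxo_name <- function(compartment, Pa, Pd, Pe, pUb) {
  stopifnot(compartment %in% c("cytoplasm", "nucleus", "DNAbound"))
  sprintf("%s_Foxo1_Pa%d_Pd%d_Pe%d_pUb%d", compartment, Pa, Pd, Pe, pUb)
}

#' All FOXO states as a data frame
#'
#' @return data.frame with columns `name`, `compartment`, `Pa`, `Pd`, `Pe`,
#'   `pUb`: 16 PTM combinations in each of 3 compartments, 48 states.
#' @export
foxo_states <- function() {
  g <- expand.grid(pUb = 0:1, Pe = 0:1, Pd = 0:1, Pa = 0:1,
                   compartment = c("cytoplasm", "nucleus", "DNAbound"),
                   stringsAsFactors = FALSE)
  g <- g[, c("compartment", "Pa", "Pd", "Pe", "pUb")]
  g$name <- with(g, foxo_name(compartment, Pa, Pd, Pe, pUb))
  g[, c("name", "compartment", "Pa", "Pd", "Pe", "pUb")]
}

#' FOXO rate table: base rates and PTM rate modifiers
#'
#' Base per-minute rates for each FOXO process and the multiplicative
#' factors ("rate MF") by which each PTM present on a molecule modifies
#' them. Factors combine multiplicatively across the marks present.
#' Second-order constants (synthesis, phosphorylation, ubiquitination,
#' degradation) are multiplied at reaction-generation time by the dynamic
#' amount of the catalysing enzyme.
#'
#' @return List with elements `base` (named base rates; second-order where an
#'   enzyme applies), `mf` (process -> PTM -> factor), `enzymes` (process ->
#'   enzyme species), `phos_factor` (kinase-specific multipliers on the basal
#'   phosphorylation constant).
#' @export
default_foxo_modifiers <- function() {
  list(
    base = c(
      synthesis = 0.0055,          # 2nd order, x E2F1
      cyt_to_nuc = 0.182,
      nuc_to_cyt = 0.055,
      nuc_to_dna = 0.25,
      dna_to_nuc = 0.125,
      phosphorylation = 5e-5,      # 2nd order, x kinase, x phos_factor
      dephosphorylation = 1e-6,    # 2nd order, x PP2A
      ubiquitination = 1e-6,       # 2nd order, x SCF/MDM2
      degradation = 1e-4),         # 2nd order, x proteasome
    mf = list(
      cyt_to_nuc = c(Pa = 0.1, Pd = 0.5, Pe = 10),
      nuc_to_cyt = c(Pa = 10, Pd = 10, Pe = 0.1),
      nuc_to_dna = c(Pa = 0.5),
      ubiquitination = c(Pa = 3, Pd = 22)),
    phos_factor = c(Pa = 6, Pd = 3, Pe = 2),
    enzymes = c(synthesis = "E2F1", Pa = "Akt_P", Pd = "IKK_P",
                Pe = "JNK_P", dephosphorylation = "PP2A",
                ubiquitination = "SCF_MDM2", degradation = "Proteasome"))
}

#' Effective per-minute rate of a FOXO process for a given PTM state
#'
#' rate = base(process) * prod over marks present of MF(process, mark).
#' Marks with no listed factor for a process leave the rate unchanged
#' (in particular pUb, which has no transport modifier).
#'
#' @param process One of the names of `table$base`.
#' @param state A row of [foxo_states()] (or any list with Pa/Pd/Pe/pUb).
#' @param table Modifier table ([default_foxo_modifiers()]).
#' @return Per-minute rate (for second-order processes, the per-enzyme
#'   constant after PTM modification).
#' @export
foxo_effective_rate <- function(process, state, table = default_foxo_modifiers()) {
  if (!process %in% names(table$base)) {
    stop("unknown FOXO process: ", process, call. = FALSE)
  }
  r <- unname(table$base[process])
  mf <- table$mf[[process]]
  for (mark in names(mf)) {
    if (isTRUE(state[[mark]] == 1)) r <- r * mf[[mark]]
  }
  r
}

#' Enumerate the FOXO species
#'
#' All 48 (compartment x PTM) states; the unmodified cytoplasmic species
#' starts at 1000 particles, all others at 0.
#'
#' @return A [species_table()].
#' @export
enumerate_foxo_species <- function() {
  st <- foxo_states()
  species_table(
    name = st$name,
    compartment = st$compartment,
    amount = ifelse(st$name == foxo_name("cytoplasm", 0, 0, 0, 0), 1000, 0),
    boundary = FALSE, scale = 1)
}

#' Generate the FOXO reactions by rule
#'
#' For every state: transport between adjacent compartments (cytoplasm <->
#' nucleus, nucleus <-> DNA-bound) at PTM-modified rates; kinase
#' phosphorylation (adds Pa/Pd/Pe; cytoplasm and nucleus, driven by the
#' dynamic amount of active kinase) with PP2A-catalysed reversal;
#' ubiquitination (cytoplasm, SCF/MDM2) modified by Pa/Pd; proteasomal
#' degradation of pUb-carrying cytoplasmic species; E2F1-driven synthesis of
#' the unmodified cytoplasmic species.
#'
#' @param states Data frame from [foxo_states()].
#' @param table Modifier table.
#' @return List of [reaction()] objects.
#' @export
generate_foxo_reactions <- function(states = foxo_states(),
                                    table = default_foxo_modifiers()) {
  rx <- list()
  add <- function(r) rx[[length(rx) + 1L]] <<- r
  enz <- table$enzymes
  swap <- function(st, field, value) { st[[field]] <- value; st }
  name_of <- function(st) foxo_name(st$compartment, st$Pa, st$Pd, st$Pe, st$pUb)

  add(reaction("Foxo_syn", products = foxo_name("cytoplasm", 0, 0, 0, 0),
               modifiers = enz[["synthesis"]],
               law = rate_law("synthesis",
                              list(k = unname(table$base["synthesis"])))))

  for (i in seq_len(nrow(states))) {
    st <- as.list(states[i, ])
    nm <- st$name
    tag <- sprintf("Pa%d_Pd%d_Pe%d_pUb%d", st$Pa, st$Pd, st$Pe, st$pUb)
    if (st$compartment == "cytoplasm") {
      add(.ma(paste0("Foxo_cn_", tag), nm,
              name_of(swap(st, "compartment", "nucleus")),
              foxo_effective_rate("cyt_to_nuc", st, table)))
    } else if (st$compartment == "nucleus") {
      add(.ma(paste0("Foxo_nc_", tag), nm,
              name_of(swap(st, "compartment", "cytoplasm")),
              foxo_effective_rate("nuc_to_cyt", st, table)))
      add(.ma(paste0("Foxo_nd_", tag), nm,
              name_of(swap(st, "compartment", "DNAbound")),
              foxo_effective_rate("nuc_to_dna", st, table)))
    } else {
      add(.ma(paste0("Foxo_dn_", tag), nm,
              name_of(swap(st, "compartment", "nucleus")),
              foxo_effective_rate("dna_to_nuc", st, table)))
    }
    # kinase marks: cytoplasm and nucleus only (DNA-bound FOXO exchanges
    # with the nucleus before being modified)
    if (st$compartment %in% c("cytoplasm", "nucleus")) {
      for (mark in c("Pa", "Pd", "Pe")) {
        if (st[[mark]] == 0) {
          add(.ma(paste0("Foxo_", st$compartment, "_", mark, "_on_", tag),
                  nm, name_of(swap(st, mark, 1)),
                  unname(table$base["phosphorylation"] *
                         table$phos_factor[mark]),
                  enz[[mark]]))
        } else {
          add(.ma(paste0("Foxo_", st$compartment, "_", mark, "_off_", tag),
                  nm, name_of(swap(st, mark, 0)),
                  unname(table$base["dephosphorylation"]),
                  enz[["dephosphorylation"]]))
        }
      }
    }
    if (st$compartment == "cytoplasm") {
      if (st$pUb == 0) {
        add(.ma(paste0("Foxo_ub_", tag), nm, name_of(swap(st, "pUb", 1)),
                foxo_effective_rate("ubiquitination", st, table),
                enz[["ubiquitination"]]))
      } else {
        add(.ma(paste0("Foxo_deg_", tag), nm, character(),
                unname(table$base["degradation"]), enz[["degradation"]]))
      }
    }
  }
  rx
}

#' Build the FOXO module (species + reactions)
#'
#' Adds the constant enzyme pools the generated reactions reference:
#' E2F1 (300), SCF/MDM2 (1000), proteasome (1000); the kinases Akt_P, IKK_P,
#' JNK_P and the phosphatase PP2A are shared with the signalling modules.
#'
#' @param table Modifier table.
#' @return Module part for [merge_modules()].
#' @export
build_foxo_module <- function(table = default_foxo_modifiers()) {
  foxo_sp <- enumerate_foxo_species()
  aux <- species_table(
    name = c("E2F1", "SCF_MDM2", "Proteasome",
             "Akt_P", "IKK_P", "JNK_P", "PP2A"),
    compartment = "cytoplasm",
    amount = c(300, 1000, 1000, 0, 0, 0, 5e5))
  sp <- rbind(foxo_sp, aux)
  class(sp) <- c("insox_species", "data.frame")
  list(species = sp, reactions = generate_foxo_reactions(foxo_states(), table))
}
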