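#' Rate laws
#'
#' The network uses a small family of rate laws, all operating on particle
#' numbers (time unit: minutes). Fluxes are particles/min and are non-negative
#' for any non-negative state.
#'
#' * `zero_order`: flux = k
#' * `mass_action`: flux = k * prod(reactant amounts) (first or second order)
#' * `catalytic`: flux = k * (sum of modifier amounts) * prod(reactant amounts)
#'   (second-order enzymatic step; the enzyme is a modifier, not consumed)
#' * `offset_mass_action`: flux = k * substrate * max(0, effector - offset).
#'   Used for Akt and PKC activation by PIP3: activation is zero at or below
#'   the basal PIP3 level (the `offset` constant).
#' * `michaelis_menten`: flux = kcat * enzyme * S / (Km + S), used for the
#'   SAPK-mediated serine phosphorylation of IRS1.
#' * `transcription`: flux = k_basal + k_stim * (sum of modifier amounts).
#'   Used for nuclear mRNA synthesis driven by DNA-bound FOXO.
#' * `synthesis`: flux = k * (sum of modifier amounts); zero order in any
#'   substrate. Used for enzyme-driven synthesis (E2F1 -> FOXO, translation).
#'
#' @param kind Rate-law kind, one of the names above.
#' @param constants Named numeric vector/list of constants. `mass_action`,
#'   `catalytic`, `synthesis` need `k`; `offset_mass_action` needs `k` and
#'   `offset`; `michaelis_menten` needs `kcat` and `Km`; `transcription` needs
#'   `k_basal` and `k_stim`; `zero_order` needs `k`.
#' @return An object of class `insox_rate_law`.
#' @export
rate_law <- function(kind, constants) {
  kinds <- c("zero_order", "mass_action", "catalytic", "offset_mass_action",
             "michaelis_menten", "transcription", "synthesis")
  if (!kind %in% kinds) {
    stop("unknown rate-law kind: ", kind, call. = FALSE)
  }
  constants <- as.list(constants)
  need <- switch(kind,
    zero_order = "k",
    mass_action = "k",
    catalytic = "k",
    synthesis = "k",
    offset_mass_action = c("k", "offset"),
    michaelis_menten = c("kcat", "Km"),
    transcription = c("k_basal", "k_stim"))
  missing <- setdiff(need, names(constants))
  if (length(missing)) {
    stop("rate law '", kind, "' missing constants: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(constants[need])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("rate-law constants must be finite and >= 0", call. = FALSE)
  }
  structure(list(kind = kind, constants = constants),
            class = "insox_rate_law")
}

#' Construct a reaction
#'
#' @param id Reaction identifier (e.g. "R1f").
#' @param reactants Character vector of species names consumed (stoichiometry
#'   1 each; repeat a name for stoichiometry 2).
#' @param products Character vector of species names produced.
#' @param modifiers Character vector of species that set the rate without
#'   being consumed (enzymes, effectors).
#' @param law An [rate_law()] object.
#' @return An object of class `insox_reaction`.
#' @export
reaction <- function(id, reactants = character(), products = character(),
                     modifiers = character(), law) {
  stopifnot(inherits(law, "insox_rate_law"), is.character(id), length(id) == 1)
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = modifiers, law = law),
            class = "insox_reaction")
}

#' Evaluate the flux of one reaction at a given state
#'
#' Direct (scalar) evaluation, used for inspection and as the reference for
#' the compiled ODE right-hand side. The flux depends only on the amounts of
#' the species the reaction names.
#'
#' @param rxn An [reaction()] object.
#' @param state Named numeric vector of species amounts (particles).
#' @return Flux in particles/min (non-negative scalar).
#' @export
evaluate_rate <- function(rxn, state) {
  stopifnot(inherits(rxn, "insox_reaction"))
  need <- unique(c(rxn$reactants, rxn$modifiers))
  missing <- setdiff(need, names(state))
  if (length(missing)) {
    stop("state is missing species referenced by ", rxn$id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(state[need] < 0)) {
    stop("negative amount passed to ", rxn$id, call. = FALSE)
  }
  cst <- rxn$law$constants
  r <- unname(state[rxn$reactants])
  m <- sum(state[rxn$modifiers])
  switch(rxn$law$kind,
    zero_order = cst$k,
    mass_action = cst$k * prod(r),
    catalytic = cst$k * m * prod(r),
    synthesis = cst$k * m,
    offset_mass_action = cst$k * prod(r) * max(0, m - cst$offset),
    michaelis_menten = cst$kcat * m * r[1] / (cst$Km + r[1]),
    transcription = cst$k_basal + cst$k_stim * m)
}
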