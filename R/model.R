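#' Compartments of the adipocyte model
#'
#' Volumes in litres. Volumes do not enter the rate laws (which act on
#' particle numbers); they are used only for particle <-> molar conversion
#' and SBML export.
#'
#' @return data.frame with columns `name`, `volume`.
#' @export
default_compartments <- function() {
  data.frame(
    name = c("extracellular", "cellsurface", "cytoplasm", "nucleus",
             "DNAbound"),
    volume = c(8.3e-12, 6.4e-14, 1.65e-11, 5e-13, 1e-13),
    stringsAsFactors = FALSE)
}

#' Construct a species table
#'
#' @param name Species identifiers.
#' @param compartment Compartment name for each species.
#' @param amount Initial amounts (model particle numbers, >= 0).
#' @param boundary Logical; boundary species are held fixed by schedules and
#'   have zero derivative (insulin, extracellular ROS).
#' @param scale Representation factor: real molecules per model particle
#'   (1000 for the ROS species, cytoplasmic SOD2 and PIP2/PIP3; 1 otherwise).
#' @return data.frame of class `insox_species`.
#' @export
species_table <- function(name, compartment, amount, boundary = FALSE,
                          scale = 1) {
  df <- data.frame(name = name, compartment = compartment, amount = amount,
                   boundary = boundary, scale = scale,
                   stringsAsFactors = FALSE)
  if (any(df$amount < 0)) stop("species amounts must be >= 0", call. = FALSE)
  class(df) <- c("insox_species", "data.frame")
  df
}

#' Assemble a model from species and reactions
#'
#' Validates the network: species names unique, every reaction reference
#' resolvable, compartments known and of positive volume.
#'
#' @param species A [species_table()].
#' @param reactions List of [reaction()] objects with unique ids.
#' @param compartments Compartment table; defaults to
#'   [default_compartments()].
#' @return An object of class `insox_model`.
#' @export
new_model <- function(species, reactions,
                      compartments = default_compartments()) {
  if (anyDuplicated(species$name)) {
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(compartments$volume <= 0)) {
    stop("compartment volumes must be > 0", call. = FALSE)
  }
  bad_comp <- setdiff(species$compartment, compartments$name)
  if (length(bad_comp)) {
    stop("unknown compartments: ", paste(bad_comp, collapse = ", "),
         call. = FALSE)
  }
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (r in reactions) {
    refs <- unique(c(r$reactants, r$products, r$modifiers))
    missing <- setdiff(refs, species$name)
    if (length(missing)) {
      stop("reaction ", r$id, " references unknown species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(species = species, reactions = reactions,
                 compartments = compartments),
            class = "insox_model")
}

#' @export
print.insox_model <- function(x, ...) {
  cat("<insox_model> ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, ",
      sum(x$species$boundary), " boundary species\n", sep = "")
  invisible(x)
}

#' Compile the ODE right-hand side of a model
#'
#' Builds a vectorized derivative function d(state)/dt = S . v(state), where
#' S is the stoichiometry matrix and v the vector of rate-law fluxes.
#' Boundary species get derivative 0. The returned closure is deterministic
#' and side-effect free; amounts are clipped at zero inside the flux
#' evaluation so that transient solver undershoot cannot generate negative
#' fluxes.
#'
#' @param model An [new_model()] object.
#' @return A list with elements `derivs` (function(t, state) -> named
#'   derivative vector), `fluxes` (function(state) -> named flux vector),
#'   `state0` (named initial state) and `reaction_ids`.
#' @export
assemble_ode <- function(model) {
  sp <- model$species$name
  nsp <- length(sp)
  rxns <- model$reactions
  nrx <- length(rxns)
  idx <- function(x) match(x, sp)

  # stoichiometry (species x reactions), boundary rows zeroed
  S <- matrix(0, nsp, nrx, dimnames = list(sp, NULL))
  for (j in seq_len(nrx)) {
    for (nm in rxns[[j]]$reactants) S[idx(nm), j] <- S[idx(nm), j] - 1
    for (nm in rxns[[j]]$products)  S[idx(nm), j] <- S[idx(nm), j] + 1
  }
  S[model$species$boundary, ] <- 0

  # modifier-sum matrix (reactions x species)
  M <- matrix(0, nrx, nsp)
  for (j in seq_len(nrx)) {
    for (nm in rxns[[j]]$modifiers) M[j, idx(nm)] <- M[j, idx(nm)] + 1
  }

  kinds <- vapply(rxns, function(r) r$law$kind, character(1))
  k1 <- numeric(nrx)   # primary constant (k or kcat or k_basal)
  k2 <- numeric(nrx)   # secondary (offset, Km, k_stim)
  i1 <- integer(nrx)   # first reactant index (0 = none)
  i2 <- integer(nrx)   # second reactant index (0 = none)
  for (j in seq_len(nrx)) {
    cst <- rxns[[j]]$law$constants
    k1[j] <- switch(kinds[j],
      michaelis_menten = cst$kcat,
      transcription = cst$k_basal,
      cst$k)
    k2[j] <- switch(kinds[j],
      offset_mass_action = cst$offset,
      michaelis_menten = cst$Km,
      transcription = cst$k_stim,
      0)
    re <- idx(rxns[[j]]$reactants)
    if (length(re) > 2) stop("at most two reactants supported", call. = FALSE)
    i1[j] <- if (length(re) >= 1) re[1] else 0L
    i2[j] <- if (length(re) >= 2) re[2] else 0L
  }
  kind_id <- match(kinds, c("zero_order", "mass_action", "catalytic",
                            "offset_mass_action", "michaelis_menten",
                            "transcription", "synthesis"))
  has1 <- i1 > 0
  has2 <- i2 > 0

  fluxes <- function(state) {
    s <- pmax(as.numeric(state), 0)
    ms <- as.numeric(M %*% s)
    r1 <- rep(1, nrx); r1[has1] <- s[i1[has1]]
    r2 <- rep(1, nrx); r2[has2] <- s[i2[has2]]
    v <- numeric(nrx)
    v[kind_id == 1L] <- k1[kind_id == 1L]
    i <- kind_id == 2L
    v[i] <- k1[i] * r1[i] * r2[i]
    i <- kind_id == 3L
    v[i] <- k1[i] * ms[i] * r1[i] * r2[i]
    i <- kind_id == 4L
    v[i] <- k1[i] * r1[i] * pmax(0, ms[i] - k2[i])
    i <- kind_id == 5L
    v[i] <- k1[i] * ms[i] * r1[i] / (k2[i] + r1[i])
    i <- kind_id == 6L
    v[i] <- k1[i] + k2[i] * ms[i]
    i <- kind_id == 7L
    v[i] <- k1[i] * ms[i]
    names(v) <- vapply(rxns, function(r) r$id, character(1))
    v
  }

  derivs <- function(t, state) {
    d <- as.numeric(S %*% fluxes(state))
    names(d) <- sp
    d
  }

  # analytic Jacobian d(dx/dt)/dx = S . dv/ds; keeps the stiff solver from
  # rebuilding it by finite differences (one build costs nsp derivative calls)
  rx_info <- lapply(seq_len(nrx), function(j) {
    list(kind = kinds[j], k1 = k1[j], k2 = k2[j],
         re = idx(rxns[[j]]$reactants), mo = idx(rxns[[j]]$modifiers))
  })
  jac <- function(t, state) {
    s <- pmax(as.numeric(state), 0)
    Dv <- matrix(0, nrx, nsp)
    for (j in seq_len(nrx)) {
      ri <- rx_info[[j]]
      re <- ri$re; mo <- ri$mo
      ms <- sum(s[mo])
      if (ri$kind == "mass_action") {
        if (length(re) == 1) {
          Dv[j, re] <- Dv[j, re] + ri$k1
        } else {
          Dv[j, re[1]] <- Dv[j, re[1]] + ri$k1 * s[re[2]]
          Dv[j, re[2]] <- Dv[j, re[2]] + ri$k1 * s[re[1]]
        }
      } else if (ri$kind == "catalytic") {
        pre <- prod(s[re])
        base <- ri$k1 * ms
        if (length(re) == 1) {
          Dv[j, re] <- Dv[j, re] + base
        } else if (length(re) == 2) {
          Dv[j, re[1]] <- Dv[j, re[1]] + base * s[re[2]]
          Dv[j, re[2]] <- Dv[j, re[2]] + base * s[re[1]]
        }
        for (m in mo) Dv[j, m] <- Dv[j, m] + ri$k1 * pre
      } else if (ri$kind == "offset_mass_action") {
        act <- max(0, ms - ri$k2)
        Dv[j, re[1]] <- Dv[j, re[1]] + ri$k1 * act
        if (ms > ri$k2) {
          for (m in mo) Dv[j, m] <- Dv[j, m] + ri$k1 * s[re[1]]
        }
      } else if (ri$kind == "michaelis_menten") {
        den <- ri$k2 + s[re[1]]
        Dv[j, re[1]] <- Dv[j, re[1]] + ri$k1 * ms * ri$k2 / den^2
        for (m in mo) Dv[j, m] <- Dv[j, m] + ri$k1 * s[re[1]] / den
      } else if (ri$kind == "transcription") {
        for (m in mo) Dv[j, m] <- Dv[j, m] + ri$k2
      } else if (ri$kind == "synthesis") {
        for (m in mo) Dv[j, m] <- Dv[j, m] + ri$k1
      }
    }
    # match the flux clipping: fluxes are flat in species held at 0
    clipped <- which(as.numeric(state) < 0)
    if (length(clipped)) Dv[, clipped] <- 0
    S %*% Dv
  }

  state0 <- stats::setNames(model$species$amount, sp)
  list(derivs = derivs, fluxes = fluxes, jacobian = jac, state0 = state0,
       reaction_ids = vapply(rxns, function(r) r$id, character(1)))
}

#' Convert particle numbers to molar concentration
#'
#' molar = amount * scale / (Avogadro * compartment volume). Scaled species
#' (ROS, cytoplasmic SOD2, PIP2/PIP3) count 1000 real molecules per model
#' particle.
#'
#' @param amount Particle number(s).
#' @param species Species name.
#' @param model Model containing the species.
#' @return Concentration(s) in mol/l.
#' @export
particles_to_concentration <- function(amount, species, model) {
  i <- match(species, model$species$name)
  if (is.na(i)) stop("unknown species: ", species, call. = FALSE)
  comp <- model$species$compartment[i]
  vol <- model$compartments$volume[match(comp, model$compartments$name)]
  if (!isTRUE(vol > 0)) stop("compartment has no positive volume", call. = FALSE)
  amount * model$species$scale[i] / (6.02214076e23 * vol)
}
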