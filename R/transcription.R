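#' Transcription/translation parameters of the FOXO target genes
#'
#' Six per-minute constants per gene: FOXO-stimulated transcription (per
#' DNA-bound FOXO molecule), basal transcription, nuclear mRNA export,
#' cytoplasmic mRNA degradation, translation (per mRNA) and protein
#' degradation.
#'
#' @return Named list of numeric vectors, one per gene (InR, SOD2).
#' @export
default_gene_params <- function() {
  list(
    InR = c(k_foxot = 0.24, k_basalt = 5.0, k_exp = 0.22, k_mdeg = 5.622,
            k_transl = 2.46, k_pdeg = 4.4e-3),
    SOD2 = c(k_foxot = 0.95, k_basalt = 15.0, k_exp = 0.22, k_mdeg = 5.622,
             k_transl = 1.23, k_pdeg = 1.9e-3))
}

# protein pool each gene feeds (shared with the signalling network)
.gene_protein <- c(InR = "InR", SOD2 = "Cytoplasm_SOD2")

#' Build the expression unit of one FOXO target gene
#'
#' Nuclear mRNA is synthesised at k_basalt + k_foxot * F, where F is the
#' instantaneous total of all DNA-bound FOXO species (every PTM state counts
#' equally), exported at k_exp, degraded in the cytoplasm at k_mdeg, and
#' translated at k_transl per mRNA into the same protein pool the signalling
#' network uses (cell-surface InR; cytoplasmic SOD2), which turns over at
#' k_pdeg.
#'
#' @param gene "InR" or "SOD2".
#' @param params Numeric vector with the six constants
#'   ([default_gene_params()]).
#' @param foxo_readout Character vector of the DNA-bound FOXO species names
#'   driving transcription.
#' @return Module part for [merge_modules()].
#' @export
build_gene <- function(gene, params = default_gene_params()[[gene]],
                       foxo_readout = dna_bound_foxo_species()) {
  if (!gene %in% names(.gene_protein)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  if (!length(foxo_readout)) {
    stop("no DNA-bound FOXO readout species supplied", call. = FALSE)
  }
  p <- as.list(params)
  protein <- .gene_protein[[gene]]
  mrna_nuc <- paste0(gene, "_mRNA_nuc")
  mrna_cyt <- paste0(gene, "_mRNA_cyt")
  sp <- species_table(
    name = c(mrna_nuc, mrna_cyt, protein),
    compartment = c("nucleus", "cytoplasm",
                    if (gene == "InR") "cellsurface" else "cytoplasm"),
    amount = c(0, 0, if (gene == "InR") 9e4 else 4.17e4),
    scale = c(1, 1, if (gene == "SOD2") 1000 else 1))
  rx <- list(
    reaction(paste0(gene, "_txn"), products = mrna_nuc,
             modifiers = foxo_readout,
             law = rate_law("transcription",
                            list(k_basal = p$k_basalt, k_stim = p$k_foxot))),
    .ma(paste0(gene, "_exp"), mrna_nuc, mrna_cyt, p$k_exp),
    .ma(paste0(gene, "_mdeg"), mrna_cyt, character(), p$k_mdeg),
    reaction(paste0(gene, "_transl"), products = protein,
             modifiers = mrna_cyt,
             law = rate_law("synthesis", list(k = p$k_transl))),
    .ma(paste0(gene, "_pdeg"), protein, character(), p$k_pdeg))
  list(species = sp, reactions = rx)
}

#' Names of the DNA-bound FOXO species
#' @return Character vector (16 names).
#' @export
dna_bound_foxo_species <- function() {
  st <- foxo_states()
  st$name[st$compartment == "DNAbound"]
}

#' Steady-state fold change of a FOXO target gene
#'
#' With mass-action transcription the steady-state protein ratio between a
#' DNA-bound FOXO level F and F = 0 is (k_basalt + k_foxot * F) / k_basalt;
#' export, mRNA degradation, translation and protein degradation cancel.
#'
#' @param params Gene parameter vector.
#' @param F DNA-bound FOXO count (>= 0).
#' @return Dimensionless fold change.
#' @export
fold_change <- function(params, F) {
  p <- as.list(params)
  if (!isTRUE(p$k_basalt > 0)) {
    stop("k_basalt must be > 0", call. = FALSE)
  }
  if (any(F < 0)) stop("F must be >= 0", call. = FALSE)
  (p$k_basalt + p$k_foxot * F) / p$k_basalt
}
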