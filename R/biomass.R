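# Condition-specific biomass reactions. Class mass fractions (g g-1 DW) are
# rescaled to sum to 1, polymer classes (protein/DNA/RNA) are expanded into
# monomer coefficients from genome-derived molar fractions using residue
# molecular weights (monomer MW minus one water per polymerized unit), and
# explicit precursors (carbohydrates, chlorophylls, lipids) use their full
# molecular weights. Coefficients are mmol g-1 DW; the MW-weighted sum of
# consumed precursors is 1000 mg g-1 DW by construction.

.MW_WATER <- 18.02

.POLYMER_CLASSES <- c(protein = "protein", dna = "dna", rna = "rna")

#' Genome-derived monomer molar fractions
#'
#' Amino-acid fractions are residue frequencies over all protein sequences;
#' dNTP fractions come from double-stranded base counts (A pairs with T and G
#' with C, so dATP = dTTP = (A+T)/2L and dGTP = dCTP = (G+C)/2L for genome
#' length L per strand); NTP fractions follow the coding-strand composition
#' with T read as U. Case and line-wrapping of the FASTA input are
#' irrelevant.
#'
#' @param genomeFasta path to the (coding-strand) genome FASTA.
#' @param proteomeFasta path to the proteome FASTA.
#' @return list with named numeric vectors \code{protein} (one-letter amino
#'   acids), \code{dna} (dATP/dCTP/dGTP/dTTP), \code{rna} (ATP/CTP/GTP/UTP),
#'   each summing to 1.
#' @export
monomerFractionsFromGenome <- function(genomeFasta, proteomeFasta) {
  genome <- Biostrings::readDNAStringSet(genomeFasta)
  prot <- Biostrings::readAAStringSet(proteomeFasta)
  if (!length(genome) || sum(Biostrings::width(genome)) == 0) {
    stop("empty genome FASTA: ", genomeFasta)
  }
  if (!length(prot) || sum(Biostrings::width(prot)) == 0) {
    stop("empty proteome FASTA: ", proteomeFasta)
  }
  aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  aa_counts <- colSums(Biostrings::letterFrequency(prot, letters = aa_letters))
  if (sum(aa_counts) == 0) stop("proteome contains no standard amino acids")
  aa <- aa_counts / sum(aa_counts)
  base <- colSums(Biostrings::letterFrequency(genome, letters = c("A", "C", "G", "T")))
  if (sum(base) == 0) stop("genome contains no A/C/G/T bases")
  at <- (base[["A"]] + base[["T"]]) / (2 * sum(base))
  gc <- (base[["C"]] + base[["G"]]) / (2 * sum(base))
  dna <- c(dATP = at, dCTP = gc, dGTP = gc, dTTP = at)
  rna <- setNames(as.numeric(base / sum(base))[c(1, 2, 3, 4)],
                  c("ATP", "CTP", "GTP", "UTP"))
  list(protein = aa, dna = dna, rna = rna)
}

#' Residue and precursor molecular weights (g mol-1)
#'
#' Standard free-monomer molecular weights for the twenty amino acids and the
#' (d)NTPs, used with the one-water polymerization correction when expanding
#' polymer classes.
#'
#' @return named numeric vector of monomer molecular weights.
#' @export
standardMonomerWeights <- function() {
  c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16,
    E = 147.13, Q = 146.15, G = 75.07, H = 155.16, I = 131.17,
    L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
    S = 105.09, T = 119.12, W = 204.23, Y = 181.19, V = 117.15,
    dATP = 491.18, dCTP = 467.16, dGTP = 507.18, dTTP = 482.17,
    ATP = 507.18, CTP = 483.16, GTP = 523.18, UTP = 484.14)
}

#' Build a condition-specific biomass reaction
#'
#' Class mass fractions are rescaled to sum to exactly 1 g g-1 DW. For a
#' polymer class with fraction f and monomer molar fractions x, the monomer
#' coefficient is \code{1000 * f * x_m / sum_k x_k (MW_k - MW_water)}
#' (mmol g-1 DW), and the polymerization water is released
#' stoichiometrically. Explicit precursor classes supply per-metabolite mass
#' fractions and use full molecular weights. The resulting reaction satisfies
#' \code{sum(coeff * residueMW) = 1000 mg g-1 DW}.
#'
#' @param classFractions named numeric, class -> g g-1 DW (classes:
#'   \code{protein}, \code{dna}, \code{rna} are polymer classes; anything
#'   else must appear in \code{precursorMasses}).
#' @param monomers monomer molar fractions per polymer class (see
#'   \code{\link{monomerFractionsFromGenome}}).
#' @param mwTable named numeric monomer/metabolite molecular weights,
#'   g mol-1 (see \code{\link{standardMonomerWeights}}).
#' @param precursorMasses named list: class -> named numeric of within-class
#'   mass fractions per metabolite id (used for non-polymer classes).
#' @param name biomass reaction name, e.g. \code{"biomass_auto_100"}.
#' @param gam growth-associated ATP maintenance, mmol g-1 DW (default 0; the
#'   hydrolysis couple is added on top of the 1 g composition when positive).
#' @return a \linkS4class{BiomassReaction}.
#' @export
buildBiomassReaction <- function(classFractions, monomers = list(),
                                 mwTable = standardMonomerWeights(),
                                 precursorMasses = list(),
                                 name = "biomass", gam = 0) {
  stopifnot(all(classFractions >= 0), sum(classFractions) > 0)
  f <- classFractions / sum(classFractions)  # rescale to 1 g g-1 DW
  coeff <- numeric(0)
  mwUsed <- numeric(0)
  water <- 0
  for (cls in names(f)) {
    if (f[[cls]] == 0) next
    if (tolower(cls) %in% names(.POLYMER_CLASSES)) {
      x <- monomers[[tolower(cls)]]
      if (is.null(x)) stop("no monomer fractions supplied for class: ", cls)
      x <- x[x > 0]
      miss <- setdiff(names(x), names(mwTable))
      if (length(miss)) stop("missing molecular weight for: ", paste(miss, collapse = ", "))
      resMW <- mwTable[names(x)] - .MW_WATER
      denom <- sum(x * resMW)
      cf <- 1000 * f[[cls]] * x / denom
      coeff[names(x)] <- (coeff[names(x)] %|0|% 0) - cf
      mwUsed[names(x)] <- resMW
      water <- water + sum(cf)
    } else {
      w <- precursorMasses[[cls]]
      if (is.null(w)) stop("no precursor masses supplied for class: ", cls)
      w <- w / sum(w)
      miss <- setdiff(names(w), names(mwTable))
      if (length(miss)) stop("missing molecular weight for: ", paste(miss, collapse = ", "))
      cf <- 1000 * f[[cls]] * w / mwTable[names(w)]
      coeff[names(w)] <- (coeff[names(w)] %|0|% 0) - cf
      mwUsed[names(w)] <- mwTable[names(w)]
    }
  }
  if (water > 0) coeff["h2o"] <- (coeff["h2o"] %|0|% 0) + water
  if (gam > 0) {
    coeff["atp"] <- (coeff["atp"] %|0|% 0) - gam
    coeff["h2o"] <- (coeff["h2o"] %|0|% 0) - gam
    coeff["adp"] <- (coeff["adp"] %|0|% 0) + gam
    coeff["pi"] <- (coeff["pi"] %|0|% 0) + gam
  }
  new("BiomassReaction", name = name, coefficients = coeff, mw = mwUsed)
}

`%|0|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

#' Mass of a biomass reaction in mg g-1 DW
#'
#' The molecular-weight-weighted sum of consumed precursors (residue weights
#' for polymer monomers); 1000 mg g-1 DW for a well-formed reaction.
#'
#' @param br a \linkS4class{BiomassReaction}.
#' @return total precursor mass, mg g-1 DW.
#' @export
biomassMass <- function(br) {
  cons <- -br@coefficients[br@coefficients < 0]
  cons <- cons[names(cons) %in% names(br@mw)]
  sum(cons * br@mw[names(cons)])
}

#' Add a biomass reaction to a model
#'
#' Creates any missing precursor metabolites (cytoplasmic by default, with
#' the molecular weights used in the reaction) and registers the reaction
#' with kind \code{biomass}. Several condition-specific biomass reactions can
#' coexist; \code{\link{applyCondition}} selects the active one.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param br a \linkS4class{BiomassReaction}.
#' @param compartment compartment for auto-created precursor metabolites.
#' @return the extended model.
#' @export
addBiomassReaction <- function(model, br, compartment = model@compartments[1]) {
  for (m in names(br@coefficients)) {
    if (!m %in% model@metabolites$id) {
      model <- addMetabolite(model, m, compartment = compartment,
                             mw = if (m %in% names(br@mw)) br@mw[[m]] else NA_real_)
    }
  }
  addReaction(model, br@name, br@coefficients, lb = 0, ub = 1000,
              kind = "biomass", subsystem = "biomass")
}

setMethod("show", "BiomassReaction", function(object) {
  cat("BiomassReaction", object@name, ":", sum(object@coefficients < 0),
      "precursors, mass", format(biomassMass(object), digits = 8), "mg g-1 DW\n")
})

#' Attach the standard media exchange reactions
#'
#' Ensures exactly eleven media exchanges: the eight nutrients (H2O, H+, Pi,
#' NH4, SO4, Fe2+, Mg2+, O2) plus the condition-specific light (photon),
#' acetate and CO2. Existing exchanges for these metabolites are reused;
#' calling twice adds nothing.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return the model with media exchanges attached.
#' @export
attachMedia <- function(model) {
  if (!"e" %in% model@compartments) model@compartments <- c(model@compartments, "e")
  for (b in .MEDIA_METS) {
    if (!is.na(.findExchange(model, b))) next
    met <- paste0(b, "_e")
    if (!met %in% model@metabolites$id) {
      model <- addMetabolite(model, met, compartment = "e")
    }
    model <- addReaction(model, paste0("EX_", met), setNames(-1, met),
                         lb = 0, ub = 1000, kind = "exchange",
                         subsystem = "media")
  }
  model
}
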