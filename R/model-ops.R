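# Structural transformations shared by the analysis modules: splitting
# reversible reactions into irreversible direction pairs and applying
# growth-condition bound sets.

#' Split reversible reactions into irreversible direction pairs
#'
#' Every reaction with \code{lb < 0 < ub} is replaced by a forward copy
#' (\code{id__fwd}, bounds \code{[0, ub]}) and a backward copy
#' (\code{id__bwd}, negated stoichiometry, bounds \code{[0, -lb]}).
#' Reactions running only backwards (\code{ub <= 0}) are negated in place
#' (recorded with \code{fwd = NA}). Net flux of the parent is
#' \code{v_fwd - v_bwd}, so any feasible flux of the original model is
#' representable after the split.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return list with the split \code{model} (all \code{lb >= 0}) and
#'   \code{mapping}, a data.frame with columns \code{parent}, \code{fwd},
#'   \code{bwd} (zero rows if the model was already irreversible).
#' @export
splitReversible <- function(model) {
  rxn <- model@reactions
  idx <- integer(0); sgn <- numeric(0)
  ids <- character(0); lb <- numeric(0); ub <- numeric(0)
  keep_cols <- c("gpr", "subsystem", "kind")
  meta <- rxn[0, keep_cols, drop = FALSE]
  map <- data.frame(parent = character(0), fwd = character(0), bwd = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rxn))) {
    r <- rxn[i, ]
    if (r$lb < 0 && r$ub > 0) {
      idx <- c(idx, i, i); sgn <- c(sgn, 1, -1)
      ids <- c(ids, paste0(r$id, "__fwd"), paste0(r$id, "__bwd"))
      lb <- c(lb, 0, 0); ub <- c(ub, r$ub, -r$lb)
      meta <- rbind(meta, r[, keep_cols], r[, keep_cols])
      map <- rbind(map, data.frame(parent = r$id, fwd = paste0(r$id, "__fwd"),
                                   bwd = paste0(r$id, "__bwd"), stringsAsFactors = FALSE))
    } else if (r$ub <= 0 && r$lb < 0) {
      idx <- c(idx, i); sgn <- c(sgn, -1)
      ids <- c(ids, paste0(r$id, "__bwd"))
      lb <- c(lb, max(0, -r$ub)); ub <- c(ub, -r$lb)
      meta <- rbind(meta, r[, keep_cols])
      map <- rbind(map, data.frame(parent = r$id, fwd = NA_character_,
                                   bwd = paste0(r$id, "__bwd"), stringsAsFactors = FALSE))
    } else {
      idx <- c(idx, i); sgn <- c(sgn, 1)
      ids <- c(ids, r$id); lb <- c(lb, r$lb); ub <- c(ub, r$ub)
      meta <- rbind(meta, r[, keep_cols])
    }
  }
  S <- model@stoichiometry[, idx, drop = FALSE] %*% Matrix::Diagonal(x = sgn)
  S <- methods::as(S, "CsparseMatrix")
  dimnames(S) <- list(model@metabolites$id, ids)
  newrxn <- data.frame(id = ids, lb = lb, ub = ub, meta,
                       stringsAsFactors = FALSE, row.names = NULL)
  obj <- model@objective
  if (nzchar(obj) && !obj %in% ids) {
    f <- map$fwd[match(obj, map$parent)]
    obj <- if (!is.na(f)) f else map$bwd[match(obj, map$parent)]
  }
  out <- model
  out@reactions <- newrxn
  out@stoichiometry <- S
  out@objective <- obj
  list(model = out, mapping = map)
}

#' Merge direction-pair fluxes back to parent net fluxes
#'
#' @param v named flux vector over a split model.
#' @param mapping the mapping returned by \code{\link{splitReversible}}.
#' @return named flux vector on the parent reaction namespace.
#' @export
mergeSplitFluxes <- function(v, mapping) {
  out <- v[!names(v) %in% c(mapping$fwd, mapping$bwd)]
  for (i in seq_len(nrow(mapping))) {
    f <- mapping$fwd[i]; b <- mapping$bwd[i]
    vf <- if (!is.na(f) && f %in% names(v)) v[[f]] else 0
    vb <- if (!is.na(b) && b %in% names(v)) v[[b]] else 0
    out[mapping$parent[i]] <- vf - vb
  }
  out
}

#' Construct a growth condition
#'
#' @param name condition name, one of \code{auto_100}, \code{auto_3k},
#'   \code{mixo}, \code{hetero} (free names allowed for custom conditions).
#' @param biomass id of the condition's biomass reaction.
#' @param overrides named list, exchange reaction id -> \code{c(lb, ub)}.
#' @return a \linkS4class{GrowthCondition}.
#' @export
growthCondition <- function(name, biomass, overrides = list()) {
  stopifnot(is.character(name), is.character(biomass))
  new("GrowthCondition", name = name, overrides = overrides, biomass = biomass)
}

# media metabolites recognized by base name (id convention <base>_e)
.NUTRIENTS <- c("h2o", "h", "pi", "nh4", "so4", "fe2", "mg2", "o2")
.MEDIA_METS <- c(.NUTRIENTS, "photon", "ac", "co2")

.findExchange <- function(model, base) {
  rxn <- model@reactions
  ex <- rxn$id[rxn$kind == "exchange"]
  for (e in ex) {
    met <- names(which(model@stoichiometry[, e] != 0))
    if (length(met) == 1 && sub("_e$", "", met) == base) return(e)
  }
  NA_character_
}

#' Build one of the four standard growth conditions for a model
#'
#' Locates the eleven media exchanges (eight nutrients plus light, acetate and
#' CO2, see \code{\link{attachMedia}}) and fills in the published bound set:
#' nutrient uptake capacity 10 mmol g-1 DW h-1 each; photon uptake 100
#' (\code{auto_100}, \code{mixo}), 3000 (\code{auto_3k}) or 0 (\code{hetero});
#' acetate uptake 2 (\code{mixo}, \code{hetero}) else 0; CO2 uptake open for
#' the light-using conditions and closed heterotrophically. Uptake is negative
#' flux, so "uptake capacity b" means \code{lb = -b}.
#'
#' @param model a \linkS4class{MetabolicModel} with media exchanges attached.
#' @param name one of \code{"auto_100"}, \code{"auto_3k"}, \code{"mixo"},
#'   \code{"hetero"}.
#' @param biomass biomass reaction id (default \code{biomass_<name>}).
#' @return a \linkS4class{GrowthCondition}.
#' @export
standardCondition <- function(model, name = c("auto_100", "auto_3k", "mixo", "hetero"),
                              biomass = paste0("biomass_", name)) {
  name <- match.arg(name)
  biomass <- biomass[1]
  ex <- vapply(.MEDIA_METS, function(b) .findExchange(model, b), character(1))
  missing <- .MEDIA_METS[is.na(ex)]
  if (length(missing)) {
    stop("missing media exchange reaction(s) for: ", paste(missing, collapse = ", "),
         " (run attachMedia() first)")
  }
  ov <- list()
  for (b in .NUTRIENTS) ov[[ex[[b]]]] <- c(-10, 1000)
  light <- switch(name, auto_100 = 100, mixo = 100, auto_3k = 3000, hetero = 0)
  ov[[ex[["photon"]]]] <- c(-light, 0)
  acet <- if (name %in% c("mixo", "hetero")) 2 else 0
  ov[[ex[["ac"]]]] <- c(-acet, 1000)
  co2lb <- if (name == "hetero") 0 else -1000
  ov[[ex[["co2"]]]] <- c(co2lb, 1000)
  growthCondition(name, biomass, ov)
}

#' Apply a growth condition to a model
#'
#' Sets the condition's exchange bounds exactly as tabulated (never widening
#' beyond the override table) and points the objective at the condition's
#' biomass reaction. Idempotent.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param cond a \linkS4class{GrowthCondition}.
#' @return the conditioned model.
#' @export
applyCondition <- function(model, cond) {
  stopifnot(is(cond, "GrowthCondition"))
  ids <- names(cond@overrides)
  missing <- setdiff(ids, model@reactions$id)
  if (length(missing)) {
    stop("condition '", cond@name, "' references missing exchange reaction(s): ",
         paste(missing, collapse = ", "))
  }
  if (!cond@biomass %in% model@reactions$id) {
    stop("biomass reaction not in model: ", cond@biomass)
  }
  for (id in ids) {
    model <- setBounds(model, id, lb = cond@overrides[[id]][1],
                       ub = cond@overrides[[id]][2])
  }
  model@objective <- cond@biomass
  model
}
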