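# Consensus protein localization and reaction compartment voting. Profiles
# are tidy data frames (protein, tool, compartment, probability); the
# consensus is the renormalized arithmetic mean across tools (equal weights,
# "wisdom of the crowd"), reactions are voted through their GPR gene sets,
# and compartments with more than `threshold` of the vote are retained.

#' Read a localization prediction table
#'
#' Expects a TSV with columns \code{protein_id}, \code{tool},
#' \code{compartment}, \code{probability}. Compartment vocabulary can be
#' harmonized through an alias map (e.g. \code{c(plastid = "chloroplast")}).
#'
#' @param path TSV path.
#' @param aliases named character vector mapping foreign compartment names to
#'   model compartment ids.
#' @return data.frame with columns \code{protein}, \code{tool},
#'   \code{compartment}, \code{probability}.
#' @export
readLocalizationTable <- function(path, aliases = character(0)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "tool", "compartment", "probability")
  if (!all(need %in% names(df))) {
    stop("localization table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(protein = df$protein_id, tool = df$tool,
                    compartment = df$compartment,
                    probability = as.numeric(df$probability),
                    stringsAsFactors = FALSE)
  hit <- out$compartment %in% names(aliases)
  out$compartment[hit] <- unname(aliases[out$compartment[hit]])
  if (any(out$probability < -1e-9 | out$probability > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]")
  }
  out
}

#' Aggregate per-tool localization predictions into a consensus
#'
#' Each tool's probability vector is renormalized (tools that omit a
#' compartment implicitly assign it 0), the vectors are averaged with equal
#' weights across tools, and the mean is renormalized so the consensus sums
#' to 1 per protein. Proteins whose probabilities are all zero are flagged
#' unlocalized and excluded.
#'
#' @param profiles data.frame (protein, tool, compartment, probability).
#' @param tools tools to include (default: all present per protein).
#' @return data.frame (protein, compartment, probability) with attribute
#'   \code{"unlocalized"} listing excluded proteins.
#' @export
aggregateToolPredictions <- function(profiles, tools = NULL) {
  stopifnot(all(c("protein", "tool", "compartment", "probability") %in% names(profiles)))
  if (!is.null(tools)) profiles <- profiles[profiles$tool %in% tools, , drop = FALSE]
  unloc <- character(0)
  res <- list()
  for (p in unique(profiles$protein)) {
    sub <- profiles[profiles$protein == p, , drop = FALSE]
    comps <- unique(sub$compartment)
    acc <- setNames(numeric(length(comps)), comps)
    ntools <- 0L
    for (tl in unique(sub$tool)) {
      v <- sub[sub$tool == tl, , drop = FALSE]
      pv <- setNames(numeric(length(comps)), comps)
      pv[v$compartment] <- v$probability
      s <- sum(pv)
      ntools <- ntools + 1L
      if (s > 0) acc <- acc + pv / s
    }
    tot <- sum(acc)
    if (tot <= 0) {
      unloc <- c(unloc, p)
      next
    }
    cons <- acc / tot
    res[[p]] <- data.frame(protein = p, compartment = names(cons),
                           probability = unname(cons), stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(protein = character(0), compartment = character(0),
               probability = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unlocalized") <- unloc
  out
}

#' Vote reactions into compartments through GPR rules
#'
#' A reaction's vote for compartment c is the mean consensus probability of c
#' over the genes in its GPR (every gene contributes \code{1/|genes|}
#' regardless of and/or structure, matching vote normalization by GPR gene
#' count). Reactions without a GPR receive no vote record; unlocalized genes
#' contribute zero mass but still count in the normalization.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param consensus consensus table from \code{\link{aggregateToolPredictions}}.
#' @return data.frame (reaction, compartment, vote).
#' @export
voteReactions <- function(model, consensus) {
  rxn <- model@reactions
  res <- list()
  for (i in seq_len(nrow(rxn))) {
    genes <- gprGenes(parseGPR(rxn$gpr[i]))
    if (!length(genes)) next
    sub <- consensus[consensus$protein %in% genes, , drop = FALSE]
    if (!nrow(sub)) next
    v <- tapply(sub$probability, sub$compartment, sum) / length(genes)
    res[[rxn$id[i]]] <- data.frame(reaction = rxn$id[i], compartment = names(v),
                                   vote = as.numeric(v), stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(reaction = character(0), compartment = character(0),
               vote = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign reactions to compartments by thresholded votes
#'
#' A reaction is retained in every compartment taking strictly more than
#' \code{threshold} of its normalized vote. If no compartment clears the
#' threshold the top-voted compartment is used (lexicographic tie-break).
#' Reactions listed in \code{fixed} receive exactly their fixed set
#' (predefined pathway-compartment constraints); reactions without a vote
#' record (no GPR) fall back to \code{default}.
#'
#' @param votes data.frame (reaction, compartment, vote).
#' @param threshold retention threshold in (0, 1); default 0.25.
#' @param fixed named list, reaction id -> character vector of compartments.
#' @param default compartment for vote-less reactions (cytoplasm by
#'   convention).
#' @param reactions optional character vector of all reaction ids that must
#'   receive an assignment (e.g. \code{reactions(model)$id}); vote-less
#'   members get \code{default}.
#' @param compartments optional vector of valid compartment ids; fixed
#'   assignments outside it raise a configuration error.
#' @return named list, reaction id -> character vector of compartments.
#' @export
assignReactionCompartments <- function(votes, threshold = 0.25, fixed = list(),
                                       default = "c", reactions = NULL,
                                       compartments = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (!is.null(compartments)) {
    badfix <- setdiff(unique(unlist(fixed)), compartments)
    if (length(badfix)) {
      stop("fixed assignment references unknown compartment(s): ",
           paste(badfix, collapse = ", "))
    }
  }
  out <- list()
  for (r in unique(votes$reaction)) {
    sub <- votes[votes$reaction == r, , drop = FALSE]
    sub <- sub[order(sub$compartment), , drop = FALSE]
    keep <- sub$compartment[sub$vote > threshold]
    if (!length(keep)) keep <- sub$compartment[which.max(sub$vote)]
    out[[r]] <- keep
  }
  for (r in names(fixed)) out[[r]] <- fixed[[r]]
  if (!is.null(reactions)) {
    for (r in setdiff(reactions, names(out))) out[[r]] <- default
  }
  out
}
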