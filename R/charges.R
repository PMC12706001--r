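#' Assign coarse-grained charges by residue type
#'
#' Side-chain charges: ASP/GLU get -1, LYS/ARG get +1, all other standard
#' residues (including HIS) 0.  In addition every chain's C-terminal bead
#' (last bead of the chain in model order) carries one extra -1 for the
#' free carboxylate.  Detyrosination therefore does not change a tail's
#' net charge: it moves the terminal -1 onto the (itself charged)
#' glutamate that becomes C-terminal, concentrating -2 on the tip bead.
#' The assignment is recomputed from scratch, so the operation is
#' idempotent.
#'
#' @param model a [bead_model()].
#' @return the model with the `charge` column replaced.
#' @export
assign_charges <- function(model) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  b <- model$beads
  bad <- !(b$residue_name %in% aa)
  if (any(bad))
    stop("unknown residue code(s) on bead_id(s): ",
         paste(b$bead_id[bad], collapse = ", "),
         " (", paste(unique(b$residue_name[bad]), collapse = ", "), ")")
  q <- numeric(nrow(b))
  q[b$residue_name %in% c("ASP", "GLU")] <- -1
  q[b$residue_name %in% c("LYS", "ARG")] <- 1
  last <- !duplicated(b$chain_id, fromLast = TRUE)
  q[last] <- q[last] - 1
  model$beads$charge <- q
  model
}

#' Set the tyrosination state of tail chains
#'
#' `state = "dY"` removes the terminal residue of each selected chain if
#' and only if that residue is TYR (the genetically encoded C-terminal
#' tyrosine of alpha-tubulin), then reassigns charges so the free
#' carboxylate -1 moves to the newly terminal glutamate.  Applying `"dY"`
#' to a chain that does not end in TYR is an error, never a silent
#' truncation.  `state = "Y"` is the identity on tyrosinated tails and
#' logs a warning on tails that are already detyrosinated (the package
#' never re-ligates a tyrosine).
#'
#' @param model a [bead_model()].
#' @param state `"Y"` or `"dY"`.
#' @param chains chain ids to edit; default: all chains in group `tail`.
#' @return the edited model, charges reassigned.
#' @export
set_tyrosination <- function(model, state = c("Y", "dY"), chains = NULL) {
  state <- match.arg(state)
  b <- model$beads
  if (is.null(chains))
    chains <- unique(b$chain_id[b$group == "tail"])
  if (length(chains) == 0) stop("no tail chains selected")
  last_idx <- vapply(chains, function(ch) max(which(b$chain_id == ch)), 1L)
  terminal <- b$residue_name[last_idx]
  if (state == "Y") {
    not_y <- terminal != "TYR"
    if (any(not_y))
      warning("chain(s) already detyrosinated, left unchanged: ",
              paste(chains[not_y], collapse = ", "))
    return(model)
  }
  not_y <- terminal != "TYR"
  if (any(not_y))
    stop("cannot detyrosinate chain(s) not ending in TYR: ",
         paste(chains[not_y], collapse = ", "))
  drop_ids <- b$bead_id[last_idx]
  keep <- !(b$bead_id %in% drop_ids)
  model$beads <- b[keep, , drop = FALSE]
  drop_ref <- function(df)
    df[!(df$i %in% drop_ids | df$j %in% drop_ids), , drop = FALSE]
  model$bonds <- drop_ref(model$bonds)
  model$native_contacts <- drop_ref(model$native_contacts)
  model$tethers <- drop_ref(model$tethers)
  assign_charges(model)
}
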