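#' Coarse-grained bead model container
#'
#' A `bead_model` holds a one-bead-per-residue representation of a molecular
#' system: bead coordinates (nm), per-bead charges (elementary charges),
#' chain/group membership, sequential backbone bonds, native contacts with
#' their rest distances, and optional inter-chain tether springs (used to
#' connect the two heads of a motor dimer).
#'
#' @param beads data.frame with columns `bead_id`, `chain_id`,
#'   `residue_index`, `residue_name` (3-letter code), `x`, `y`, `z` (nm),
#'   `charge`, `group`, `anchored` (logical: positionally restrained during
#'   dynamics).
#' @param bonds data.frame with columns `i`, `j` (bead_ids), sequential
#'   backbone bonds within a chain.
#' @param native_contacts data.frame with columns `i`, `j`, `r0` (nm) and
#'   optionally `eps` (kcal/mol; `NA` means use the force-field default).
#' @param tethers data.frame with columns `i`, `j`: soft inter-chain springs.
#' @return an object of class `bead_model`.
#' @export
bead_model <- function(beads,
                       bonds = empty_bonds(),
                       native_contacts = empty_contacts(),
                       tethers = empty_bonds()) {
  required <- c("bead_id", "chain_id", "residue_index", "residue_name",
                "x", "y", "z", "charge", "group", "anchored")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols) > 0)
    stop("beads is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(beads$bead_id))
    stop("bead_ids must be unique")
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("all bead positions must be finite")
  if (nrow(native_contacts) > 0 && any(native_contacts$r0 <= 0))
    stop("native contact distances must be > 0")
  if (nrow(bonds) > 0) {
    ci <- beads$chain_id[match(bonds$i, beads$bead_id)]
    cj <- beads$chain_id[match(bonds$j, beads$bead_id)]
    if (any(is.na(ci)) || any(is.na(cj)))
      stop("bond references unknown bead_id")
    if (any(ci != cj))
      stop("bonds must connect beads within one chain")
  }
  if (!"eps" %in% names(native_contacts) && nrow(native_contacts) > 0)
    native_contacts$eps <- NA_real_
  structure(list(beads = beads, bonds = bonds,
                 native_contacts = native_contacts, tethers = tethers),
            class = "bead_model")
}

empty_bonds <- function() data.frame(i = integer(), j = integer())
empty_contacts <- function()
  data.frame(i = integer(), j = integer(), r0 = numeric(), eps = numeric())

#' @export
print.bead_model <- function(x, ...) {
  b <- x$beads
  cat("bead_model:", nrow(b), "beads,", length(unique(b$chain_id)),
      "chains,", nrow(x$bonds), "bonds,", nrow(x$native_contacts),
      "native contacts\n")
  tab <- table(b$group)
  cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  net charge:", sum(b$charge), "e\n")
  invisible(x)
}

#' Coordinates of a bead model as a matrix
#' @param model a `bead_model`.
#' @return numeric matrix (n beads x 3), nm.
#' @export
coords <- function(model) {
  as.matrix(model$beads[, c("x", "y", "z")])
}

#' Center of geometry of a bead selection
#' @param model a `bead_model`.
#' @param ids bead_ids to average over (default: all beads).
#' @return length-3 numeric vector, nm.
#' @export
center_of_geometry <- function(model, ids = model$beads$bead_id) {
  sel <- model$beads$bead_id %in% ids
  colMeans(coords(model)[sel, , drop = FALSE])
}

#' Merge two bead models into one
#'
#' Bead ids of `b` are shifted to stay unique; chain ids must not collide.
#' @param a,b `bead_model` objects.
#' @return a `bead_model` containing both systems.
#' @export
merge_models <- function(a, b) {
  if (length(intersect(a$beads$chain_id, b$beads$chain_id)) > 0)
    stop("chain_id collision between models")
  shift <- max(a$beads$bead_id)
  bb <- b$beads
  bb$bead_id <- bb$bead_id + shift
  shift_df <- function(df) {
    if (nrow(df) == 0) return(df)
    df$i <- df$i + shift
    df$j <- df$j + shift
    df
  }
  bead_model(rbind(a$beads, bb),
             rbind(a$bonds, shift_df(b$bonds)),
             rbind(a$native_contacts, shift_df(b$native_contacts)),
             rbind(a$tethers, shift_df(b$tethers)))
}

# Deterministic quasi-uniform points on a unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
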