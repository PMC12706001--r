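#' Generate a toy two-headed motor (low/high-affinity head pair)
#'
#' A rigid quasi-spherical head of `n_body_beads` beads with a designated
#' binding face at the bottom (-z): the `length(face_charges)` lowest
#' beads carry the given charges (encoded as LYS/ASP/GLY residues so that
#' [assign_charges()] reproduces them).  The default face mimics the
#' basic-residue cluster of the dynein-2 microtubule-binding domain
#' (K2996/R3007/K3077-K3080-R3081 analogues): four +1 beads.  Internal
#' rigidity is enforced by an all-pairs network of stiff native contacts.
#' Two copies are returned, groups `mtbd_low` and `mtbd_high`; the
#' topmost bead of each head is the tether attachment (and chain
#' C-terminus).
#'
#' @param n_body_beads beads per head (>= 4).
#' @param face_charges integer charges (-1/0/+1) of the face beads.
#' @param tether_length nm, rest length of the inter-head tether spring.
#' @param seed integer; a small deterministic jitter (0.02 nm) is drawn
#'   from it so distinct seeds give distinct (but reproducible) bodies.
#' @param radius nm, head radius.
#' @param rigidity_eps kcal/mol, depth of the internal contact network.
#' @return list with elements `low` and `high` ([bead_model()]s) and
#'   `tether_length`.
#' @export
gen_toy_motor <- function(n_body_beads = 12, face_charges = c(1, 1, 1, 1),
                          tether_length = 12, seed = 1, radius = 1.2,
                          rigidity_eps = 10) {
  if (n_body_beads < 4) stop("n_body_beads must be >= 4")
  if (!all(face_charges %in% c(-1, 0, 1)))
    stop("face_charges must be -1, 0 or +1")
  if (length(face_charges) > n_body_beads)
    stop("more face charges than beads")
  xyz <- fibonacci_sphere(n_body_beads) * radius
  ord <- order(xyz[, 3])               # face (lowest z) first, top last
  xyz <- xyz[ord, , drop = FALSE]
  set.seed(seed)
  xyz <- xyz + matrix(rnorm(3 * n_body_beads, sd = 0.02), ncol = 3)
  res <- rep("GLY", n_body_beads)
  res[seq_along(face_charges)][face_charges == 1] <- "LYS"
  res[seq_along(face_charges)][face_charges == -1] <- "ASP"
  one_head <- function(chain, group) {
    beads <- data.frame(
      bead_id = seq_len(n_body_beads), chain_id = chain,
      residue_index = seq_len(n_body_beads), residue_name = res,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = 0, group = group, anchored = group == "mtbd_high")
    pairs <- which(upper.tri(diag(n_body_beads)), arr.ind = TRUE)
    d <- sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2))
    nc <- data.frame(i = pairs[, 1], j = pairs[, 2], r0 = d,
                     eps = rigidity_eps)
    assign_charges(bead_model(beads, native_contacts = nc))
  }
  list(low = one_head("ML", "mtbd_low"),
       high = one_head("MH", "mtbd_high"),
       tether_length = tether_length)
}

#' Placement of the two motor heads on the lattice
#'
#' `position_id` gives the axial offset of the high-affinity head relative
#' to the low-affinity head on the adjacent protofilament: 1 = backward
#' (high head trailing, one site toward the plus end), 2 = lateral (zero
#' axial offset), 3 = forward (high head leading, one site toward the
#' minus end).  These map onto the cryo-ET dimer Configurations 1-3.
#'
#' @param position_id 1, 2 or 3.
#' @return object of class `placement_spec`.
#' @export
placement_spec <- function(position_id) {
  if (!position_id %in% 1:3) stop("position_id must be 1, 2 or 3")
  structure(list(position_id = as.integer(position_id),
                 axial_offset = c(-1L, 0L, 1L)[position_id]),
            class = "placement_spec")
}

#' Place a motor dimer on a tubulin lattice
#'
#' Translates the low-affinity head so its center of geometry coincides
#' with grid site (1,1); the high-affinity head is placed on the adjacent
#' protofilament (grid column 2) at axial site offset -1/0/+1 for
#' positions 1/2/3 and is positionally anchored for the whole run (the
#' high-affinity state does not change during the simulated initial
#' diffusion of the low-affinity head).  The two heads are connected by
#' a soft tether spring standing in for dimerization.  The low-affinity
#' head is held only by charge complementarity with the lattice surface
#' and E-hooks — the low-affinity state has no strong canonical
#' interface; set `docking_contacts = TRUE` to additionally generate
#' structure-based contacts at the placed geometry (a docked-pose
#' proxy).  Lattice coordinates are never modified.
#'
#' @param lattice a lattice [bead_model()] from [build_lattice()].
#' @param motor a motor pair from [gen_toy_motor()].
#' @param placement a [placement_spec()].
#' @param grid a [site_grid()] (e.g. [default_grid()]).
#' @param docking_contacts generate native contacts between the low head
#'   and nearby lattice body beads at the placed geometry.
#' @param contact_cutoff nm: pair cutoff for `docking_contacts`.
#' @return the combined [bead_model()].
#' @export
place_dimer <- function(lattice, motor, placement, grid,
                        docking_contacts = FALSE, contact_cutoff = 2.0) {
  spec <- attr(lattice, "lattice_spec")
  if (!is.null(spec) && (spec$n_pf < 2 || spec$n_dimers_per_pf < 3))
    stop("lattice must have >= 2 PFs and >= 3 dimers per PF")
  if (!inherits(placement, "placement_spec"))
    placement <- placement_spec(placement)
  center_low <- grid$site_centers[grid$row == 1 & grid$col == 1, ]
  hi_row <- 1L + placement$axial_offset
  hi_sel <- grid$row == hi_row & grid$col == 2
  if (!any(hi_sel)) stop("placement falls outside the lattice grid")
  center_high <- grid$site_centers[hi_sel, ]
  move_to <- function(head, target) {
    shift <- target - center_of_geometry(head)
    head$beads$x <- head$beads$x + shift[1]
    head$beads$y <- head$beads$y + shift[2]
    head$beads$z <- head$beads$z + shift[3]
    head
  }
  low <- move_to(motor$low, center_low)
  high <- move_to(motor$high, center_high)
  sys <- merge_models(merge_models(lattice, low), high)
  b <- sys$beads
  if (docking_contacts) {
    low_ids <- b$bead_id[b$group == "mtbd_low"]
    body_ids <- b$bead_id[b$group %in% c("alpha_tubulin", "beta_tubulin")]
    xyz <- coords(sys)
    li <- match(low_ids, b$bead_id); bi <- match(body_ids, b$bead_id)
    dmat <- sqrt(outer(rowSums(xyz[li, ]^2), rowSums(xyz[bi, ]^2), "+") -
                   2 * xyz[li, ] %*% t(xyz[bi, ]))
    hit <- which(dmat <= contact_cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      nc <- data.frame(i = low_ids[hit[, 1]], j = body_ids[hit[, 2]],
                       r0 = dmat[hit], eps = NA_real_)
      sys$native_contacts <- rbind(sys$native_contacts, nc)
    }
  }
  top_of <- function(grp) {
    ids <- b$bead_id[b$group == grp]
    ids[which.max(b$z[match(ids, b$bead_id)])]
  }
  sys$tethers <- rbind(sys$tethers,
                       data.frame(i = top_of("mtbd_low"),
                                  j = top_of("mtbd_high")))
  attr(sys, "lattice_spec") <- spec
  attr(sys, "placement") <- placement
  attr(sys, "tether_length") <- motor$tether_length
  sys
}
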