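#' Specification of an idealized tubulin lattice
#'
#' Geometry defaults: 8.2 nm axial rise per tubulin dimer, 5.2 nm lateral
#' protofilament (PF) spacing, 0.92 nm B-lattice stagger between adjacent
#' PFs, straight parallel PFs (no supertwist or curvature).  Each tubulin
#' monomer is a reduced rigid body of `beads_per_monomer` beads
#' approximating the surface footprint; each alpha-tubulin carries a fully
#' flexible C-terminal tail (E-hook) of sequence `tail_sequence` whose
#' terminal tyrosine can be present (`"Y"`) or enzymatically removed
#' (`"dY"`).
#'
#' @param n_pf number of protofilaments (>= 1).
#' @param n_dimers_per_pf tubulin dimers per PF (>= 1).
#' @param axial_rise_per_dimer nm, axial spacing of dimers along a PF.
#' @param lateral_spacing nm, spacing between adjacent PFs.
#' @param stagger nm, B-lattice axial stagger between adjacent PFs.
#' @param tail_sequence one-letter amino-acid sequence of the alpha-tubulin
#'   C-terminal tail, N- to C-terminus.  The default is the C-terminal
#'   E-hook segment of Chlamydomonas alpha-tubulin ending in the
#'   genetically encoded tyrosine.
#' @param tail_state `"Y"` or `"dY"`, scalar or one value per alpha-tubulin.
#' @param beads_per_monomer beads in each reduced rigid tubulin body.
#' @param monomer_radius nm, radius of the reduced body.
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(n_pf = 4, n_dimers_per_pf = 3,
                         axial_rise_per_dimer = 8.2,
                         lateral_spacing = 5.2,
                         stagger = 0.92,
                         tail_sequence = "DFEEVGAESAEGAGEGEGEEY",
                         tail_state = "Y",
                         beads_per_monomer = 20,
                         monomer_radius = 1.6) {
  if (n_pf < 1 || n_dimers_per_pf < 1)
    stop("n_pf and n_dimers_per_pf must be >= 1")
  if (axial_rise_per_dimer <= 0 || lateral_spacing <= 0)
    stop("axial_rise_per_dimer and lateral_spacing must be > 0")
  if (nchar(tail_sequence) == 0)
    stop("tail_sequence must be non-empty")
  if (!all(tail_state %in% c("Y", "dY")))
    stop("tail_state values must be 'Y' or 'dY'")
  n_tails <- n_pf * n_dimers_per_pf
  if (!length(tail_state) %in% c(1L, n_tails))
    stop("tail_state must be scalar or one value per alpha-tubulin")
  structure(list(n_pf = as.integer(n_pf),
                 n_dimers_per_pf = as.integer(n_dimers_per_pf),
                 axial_rise_per_dimer = axial_rise_per_dimer,
                 lateral_spacing = lateral_spacing,
                 stagger = stagger,
                 tail_sequence = tail_sequence,
                 tail_state = rep(tail_state, length.out = n_tails),
                 beads_per_monomer = as.integer(beads_per_monomer),
                 monomer_radius = monomer_radius),
            class = "lattice_spec")
}

# One reduced tubulin body: beads_per_monomer points on a sphere, reordered
# so the outermost (max z, i.e. lattice-surface) bead is the chain
# C-terminus; for alpha-tubulin that bead is the tail attachment point and
# the next two outermost beads are glutamates standing in for the exposed
# acidic surface cluster (E411/E420/E423 region of the H11-H12 face).
monomer_body <- function(center, spec, is_alpha) {
  n <- spec$beads_per_monomer
  xyz <- fibonacci_sphere(n) * spec$monomer_radius
  ord <- order(xyz[, 3])             # ascending z: outermost last
  xyz <- xyz[ord, , drop = FALSE]
  res <- rep("GLY", n)
  if (is_alpha && n >= 3)
    res[c(n - 2L, n - 1L)] <- "GLU"
  list(xyz = sweep(xyz, 2, center, "+"), residue_name = res)
}

#' Build an idealized coarse-grained tubulin lattice
#'
#' Deterministically constructs `n_pf * n_dimers_per_pf` tubulin dimers
#' (rigid alpha and beta bodies, positionally anchored during dynamics)
#' with one flexible tail chain per alpha-tubulin, then assigns charges via
#' [assign_charges()] and applies the requested tyrosination state.
#'
#' @param spec a [lattice_spec()].
#' @return a [bead_model()] with groups `alpha_tubulin`, `beta_tubulin`,
#'   `tail`.
#' @export
build_lattice <- function(spec) {
  if (!inherits(spec, "lattice_spec")) stop("spec must be a lattice_spec")
  tail3 <- aa_three(spec$tail_sequence)
  n_tail <- length(tail3)
  rows <- list()
  bonds_i <- integer(); bonds_j <- integer()
  bid <- 0L
  tail_chain_ids <- character()
  for (p in seq_len(spec$n_pf)) {
    for (d in seq_len(spec$n_dimers_per_pf)) {
      x0 <- (d - 1L) * spec$axial_rise_per_dimer + (p - 1L) * spec$stagger
      y0 <- (p - 1L) * spec$lateral_spacing
      for (mono in c("A", "B")) {
        is_alpha <- mono == "A"
        cx <- if (is_alpha) x0 else x0 + spec$axial_rise_per_dimer / 2
        body <- monomer_body(c(cx, y0, 0), spec, is_alpha)
        chain <- sprintf("%s_p%d_d%d", mono, p, d)
        n <- nrow(body$xyz)
        rows[[length(rows) + 1L]] <- data.frame(
          bead_id = bid + seq_len(n), chain_id = chain,
          residue_index = seq_len(n), residue_name = body$residue_name,
          x = body$xyz[, 1], y = body$xyz[, 2], z = body$xyz[, 3],
          charge = 0,
          group = if (is_alpha) "alpha_tubulin" else "beta_tubulin",
          anchored = TRUE)
        bonds_i <- c(bonds_i, bid + seq_len(n - 1L))
        bonds_j <- c(bonds_j, bid + seq_len(n - 1L) + 1L)
        attach <- c(cx, y0, spec$monomer_radius)  # C-terminal surface bead
        bid <- bid + n
        if (is_alpha) {
          chain_t <- sprintf("T_p%d_d%d", p, d)
          tail_chain_ids <- c(tail_chain_ids, chain_t)
          tz <- attach[3] + 0.38 * seq_len(n_tail)
          rows[[length(rows) + 1L]] <- data.frame(
            bead_id = bid + seq_len(n_tail), chain_id = chain_t,
            residue_index = seq_len(n_tail), residue_name = tail3,
            x = attach[1], y = attach[2], z = tz,
            charge = 0, group = "tail",
            anchored = c(TRUE, rep(FALSE, n_tail - 1L)))
          bonds_i <- c(bonds_i, bid + seq_len(n_tail - 1L))
          bonds_j <- c(bonds_j, bid + seq_len(n_tail - 1L) + 1L)
          bid <- bid + n_tail
        }
      }
    }
  }
  model <- bead_model(do.call(rbind, rows),
                      data.frame(i = bonds_i, j = bonds_j))
  model <- assign_charges(model)
  dy <- tail_chain_ids[spec$tail_state == "dY"]
  if (length(dy) > 0)
    model <- set_tyrosination(model, "dY", chains = dy)
  attr(model, "lattice_spec") <- spec
  model
}

#' 3x3 binding-site grid for occupancy analysis
#'
#' The grid of nine binding-site centers used to bin the mobile head's
#' center-of-geometry trajectory.  Index `(1, 1)` (0-based rows/columns
#' 0..2) is the central site, the initial position of the low-affinity
#' head.  The capture region is the Voronoi partition of the nine centers
#' in the axial/lateral plane, clipped to the grid bounding rectangle
#' extended by half a site spacing per axis; positions above
#' `detach_height` over the lattice surface, or outside the clipped
#' rectangle, are OVERFLOW.
#'
#' @param center 3-vector, nm: position of the central site (1,1).
#' @param axial_spacing nm, site spacing along the axial direction.
#' @param lateral_spacing nm, site spacing along the lateral direction.
#' @param axial unit 3-vector toward the microtubule minus end (the
#'   direction of dynein movement).
#' @param lateral unit 3-vector across protofilaments.
#' @param normal unit 3-vector, outward lattice surface normal.
#' @param surface_z nm, height of the lattice surface along `normal`.
#' @param detach_height nm above the surface beyond which the head counts
#'   as detached.
#' @return object of class `site_grid`.
#' @export
site_grid <- function(center, axial_spacing = 8.2, lateral_spacing = 5.2,
                      axial = c(1, 0, 0), lateral = c(0, 1, 0),
                      normal = c(0, 0, 1), surface_z = 1.6,
                      detach_height = 6) {
  axial <- axial / sqrt(sum(axial^2))
  lateral <- lateral / sqrt(sum(lateral^2))
  if (abs(sum(axial * lateral)) > 1e-9)
    stop("axial and lateral directions must be orthogonal")
  centers <- matrix(NA_real_, 9, 3)
  idx <- expand.grid(row = 0:2, col = 0:2)
  for (k in seq_len(9)) {
    centers[k, ] <- center + (idx$row[k] - 1) * axial_spacing * axial +
      (idx$col[k] - 1) * lateral_spacing * lateral
  }
  structure(list(site_centers = centers, row = idx$row, col = idx$col,
                 center = center,
                 axial_direction = axial, lateral_direction = lateral,
                 normal = normal / sqrt(sum(normal^2)),
                 axial_spacing = axial_spacing,
                 lateral_spacing = lateral_spacing,
                 margin_axial = axial_spacing / 2,
                 margin_lateral = lateral_spacing / 2,
                 surface_z = surface_z, detach_height = detach_height),
            class = "site_grid")
}

#' Default site grid for a lattice with a placed dimer
#'
#' Convenience constructor: centers the grid on the low-affinity head's
#' initial site of a lattice built from `spec` (central PF, central dimer).
#'
#' @param spec a [lattice_spec()].
#' @param height nm, height of the site centers above the body center
#'   plane (defaults to the motor-resting height used by [place_dimer()]).
#' @param motor_radius nm, radius of the toy motor head.
#' @return a [site_grid()].
#' @export
default_grid <- function(spec, motor_radius = 1.2,
                         height = spec$monomer_radius + motor_radius + 0.1) {
  p_low <- low_pf(spec)
  d_low <- ceiling(spec$n_dimers_per_pf / 2)
  x <- (d_low - 1) * spec$axial_rise_per_dimer +
    (p_low - 1) * spec$stagger + spec$axial_rise_per_dimer / 4
  site_grid(center = c(x, (p_low - 1) * spec$lateral_spacing, height),
            axial_spacing = spec$axial_rise_per_dimer,
            lateral_spacing = spec$lateral_spacing,
            surface_z = spec$monomer_radius)
}

low_pf <- function(spec) max(1L, spec$n_pf %/% 2L)
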