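# Shared builders for small test systems.

tiny_spec <- function(...) lattice_spec(beads_per_monomer = 8, ...)

# A minimal free bead model: n beads on one flexible chain.
chain_model <- function(n, spacing = 0.38, residue = "GLY",
                        group = "tail", anchored_first = FALSE) {
  beads <- data.frame(bead_id = seq_len(n), chain_id = "C1",
                      residue_index = seq_len(n),
                      residue_name = rep_len(residue, n),
                      x = 0, y = 0, z = spacing * seq_len(n),
                      charge = 0, group = group,
                      anchored = c(anchored_first, rep(FALSE, n - 1)))
  bonds <- if (n > 1) data.frame(i = 1:(n - 1), j = 2:n) else
    data.frame(i = integer(), j = integer())
  bead_model(beads, bonds)
}

# Arbitrary rigid motion for invariance tests.
rigid_motion <- function(xyz, angles = c(0.3, -1.1, 2.0),
                         shift = c(5, -3, 7)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                             0, sin(a), cos(a)), 3, 3)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                             0, 0, 1), 3, 3)
  rot <- rx(angles[1]) %*% rz(angles[2]) %*% rx(angles[3])
  sweep(xyz %*% t(rot), 2, shift, "+")
}

apply_motion <- function(model, ...) {
  xyz <- rigid_motion(coords(model), ...)
  model$beads$x <- xyz[, 1]; model$beads$y <- xyz[, 2]
  model$beads$z <- xyz[, 3]
  model
}

# Build a cg_trajectory by hand from a COM series.
fake_traj <- function(com, com_high = NULL, position_id = 2, stride = 1) {
  com <- as.matrix(com)
  if (is.null(com_high)) com_high <- com * 0
  structure(list(steps = stride * seq_len(nrow(com)), com_low = com,
                 com_high = as.matrix(com_high),
                 metadata = list(seed = 0, position_id = position_id)),
            class = "cg_trajectory")
}

# Write a tiny PDB file with CA atoms at given nm coordinates.
write_tiny_pdb <- function(xyz_nm, path, chain = "A",
                           resnames = rep("GLY", nrow(xyz_nm))) {
  a <- xyz_nm * 10
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(a)), resnames, chain, seq_len(nrow(a)),
    a[, 1], a[, 2], a[, 3])
  writeLines(c(lines, "END"), path)
  path
}

# The toy campaign used by the acceptance checks; run once per test
# session and memoized (it is the expensive scaled-down stand-in for the
# full simulation protocol).
.camp_env <- new.env(parent = emptyenv())
toy_campaign <- function() {
  if (is.null(.camp_env$camp))
    .camp_env$camp <- run_campaign(n_seeds = 10, base_seed = 1)
  .camp_env$camp
}
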