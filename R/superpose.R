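#' Optimal rigid-body superposition RMSD (Kabsch)
#'
#' Pairs beads of the two models 1:1 by residue index within the given
#' selections (after applying `offset_b`, the residue-numbering offset of
#' model B relative to model A), removes the centroids, and solves for the
#' least-squares rotation by singular value decomposition with the
#' determinant correction that excludes reflections.  Returns the minimal
#' RMSD in Angstrom (coordinates are stored in nm; 1 nm = 10 A).
#'
#' The default selections are the microtubule-binding-domain construct
#' bounds of human dynein-2 (residues 2962-3126) and human dynein-1
#' (residues 3266-3429); pairing is by index offset, no internal sequence
#' alignment is performed.
#'
#' @param model_a,model_b [bead_model()]s.
#' @param selection_a,selection_b integer vectors of residue indices; by
#'   default all residues of each model.
#' @param offset_b residue-index offset added to `selection_a` indices to
#'   find partners in model B; if `NULL`, selections are paired in sorted
#'   order and must have equal lengths.
#' @return RMSD in Angstrom (numeric scalar).
#' @export
superpose_rmsd <- function(model_a, model_b,
                           selection_a = NULL, selection_b = NULL,
                           offset_b = NULL) {
  get_xyz <- function(model, sel) {
    b <- model$beads
    if (!is.null(sel)) b <- b[b$residue_index %in% sel, , drop = FALSE]
    b <- b[order(b$residue_index), , drop = FALSE]
    list(xyz = as.matrix(b[, c("x", "y", "z")]), res = b$residue_index)
  }
  a <- get_xyz(model_a, selection_a)
  b <- get_xyz(model_b, selection_b)
  if (!is.null(offset_b)) {
    common <- intersect(a$res + offset_b, b$res)
    a$xyz <- a$xyz[match(common - offset_b, a$res), , drop = FALSE]
    b$xyz <- b$xyz[match(common, b$res), , drop = FALSE]
  }
  if (nrow(a$xyz) != nrow(b$xyz))
    stop("mismatched selection lengths (", nrow(a$xyz), " vs ",
         nrow(b$xyz), "); supply offset_b for index pairing")
  if (nrow(a$xyz) < 3) stop("need at least 3 paired beads")
  kabsch_rmsd(a$xyz, b$xyz) * 10
}

# Minimal least-squares RMSD over proper rotations + translation, nm in/out.
kabsch_rmsd <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  s <- svd(crossprod(pc, qc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  pr <- pc %*% t(rot)
  sqrt(mean(rowSums((pr - qc)^2)))
}
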