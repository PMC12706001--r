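#' Debye-Hueckel screened electrostatic pair energy
#'
#' U(r) = kB T * lB * qi qj * exp(-r / lD) / r, with the Bjerrum length lB
#' and Debye length lD computed from the simulation conditions by their
#' closed forms.  The prefactor kB T * lB equals e^2 / (4 pi eps eps0)
#' and is evaluated in that temperature-independent form, so the
#' deterministic zero-temperature testing limit remains well defined
#' (the screening length is then taken at the 300 K reference).
#'
#' @param qi,qj elementary charges.
#' @param r nm (> 0).
#' @param params a [sim_params()].
#' @return kcal/mol.
#' @export
debye_huckel_energy <- function(qi, qj, r, params = sim_params()) {
  if (any(r <= 0)) stop("r must be > 0")
  pref <- dh_prefactor(params$dielectric)
  t_len <- if (params$temperature > 0) params$temperature else 300
  screen <- if (params$ionic_strength > 0)
    exp(-r / debye_length(params$ionic_strength, t_len,
                          params$dielectric)) else 1
  pref * qi * qj * screen / r
}

# e^2 / (4 pi eps eps0) in kcal nm / mol: equals kB T times the Bjerrum
# length at any temperature.
dh_prefactor <- function(dielectric) {
  .e_C^2 * .NA_mol / (4 * pi * .eps0 * dielectric) / 4184 * 1e9
}

#' 12-10 Go native-contact pair energy
#'
#' U(r) = eps * (5 (r0/r)^12 - 6 (r0/r)^10); minimum -eps at r = r0,
#' tending to 0 as r grows.
#'
#' @param r nm (> 0).
#' @param r0 native distance, nm (> 0).
#' @param eps well depth, kcal/mol.
#' @return kcal/mol.
#' @export
go_contact_energy <- function(r, r0, eps) {
  if (any(r <= 0) || any(r0 <= 0)) stop("r and r0 must be > 0")
  s <- r0 / r
  eps * (5 * s^12 - 6 * s^10)
}

#' Purely repulsive excluded-volume pair energy
#'
#' eps * (sigma/r)^12, shifted so the energy is continuous (zero) at the
#' cutoff and exactly zero beyond it.
#'
#' @param r nm (> 0).
#' @param sigma nm.
#' @param eps kcal/mol.
#' @param cutoff nm (default 2 sigma).
#' @return kcal/mol.
#' @export
excluded_volume_energy <- function(r, sigma, eps, cutoff = 2 * sigma) {
  if (any(r <= 0)) stop("r must be > 0")
  shift <- eps * (sigma / cutoff)^12
  ifelse(r < cutoff, eps * (sigma / r)^12 - shift, 0)
}

#' Total potential energy of an assembled system, by component
#'
#' Pure-R reference evaluation of the engine's potential: per-term
#' breakdown (bonded, angle, native, electrostatic, excluded, restraint,
#' tether) plus the total.  Bond and angle rest geometry is the model's
#' built geometry, as in the engine.  Used as the independent cross-check
#' of the compiled integrator's energy accounting.
#'
#' @param model a [bead_model()] (charged and topologized).
#' @param params a [sim_params()].
#' @param ff a [force_field()].
#' @param ref_model optional model giving the rest geometry (defaults to
#'   `model` itself, i.e. the current coordinates are the rest geometry).
#' @return named numeric vector of components and `total`, kcal/mol.
#' @export
total_energy <- function(model, params = sim_params(),
                         ff = force_field(params = params),
                         ref_model = model) {
  xyz <- coords(model)
  ref <- coords(ref_model)
  b <- model$beads
  id2row <- function(id) match(id, b$bead_id)
  pair_r <- function(df, coords_mat) {
    i <- id2row(df$i); j <- id2row(df$j)
    sqrt(rowSums((coords_mat[i, , drop = FALSE] -
                    coords_mat[j, , drop = FALSE])^2))
  }
  e_bond <- 0
  if (nrow(model$bonds) > 0) {
    r <- pair_r(model$bonds, xyz)
    r0 <- pair_r(model$bonds, ref)
    e_bond <- sum(0.5 * ff$bond_k * (r - r0)^2)
  }
  e_angle <- 0
  ang <- chain_angles(model)
  if (nrow(ang) > 0) {
    th <- bead_angle(xyz, id2row(ang$i), id2row(ang$j), id2row(ang$k))
    th0 <- bead_angle(ref, id2row(ang$i), id2row(ang$j), id2row(ang$k))
    e_angle <- sum(0.5 * ff$angle_k * (th - th0)^2)
  }
  e_native <- 0
  nc <- model$native_contacts
  if (nrow(nc) > 0) {
    eps <- ifelse(is.na(nc$eps), ff$go_epsilon, nc$eps)
    e_native <- sum(go_contact_energy(pair_r(nc, xyz), nc$r0, eps))
  }
  np <- nonbonded_pairs(model)
  e_elec <- 0; e_ev <- 0
  if (nrow(np) > 0) {
    r <- sqrt(rowSums((xyz[np$i, , drop = FALSE] -
                         xyz[np$j, , drop = FALSE])^2))
    if (any(r == 0)) stop("overlapping beads at r = 0")
    qq <- b$charge[np$i] * b$charge[np$j]
    el <- qq != 0 & r < ff$elec_cutoff
    if (any(el))
      e_elec <- sum(debye_huckel_energy(b$charge[np$i[el]],
                                        b$charge[np$j[el]], r[el], params))
    sig <- (bead_ev_sigma(b$residue_name[np$i], ff) +
              bead_ev_sigma(b$residue_name[np$j], ff)) / 2
    ev <- np$ev & r < pmin(ff$ev_cutoff, 2 * sig)
    if (any(ev))
      e_ev <- sum(vapply(which(ev), function(k)
        excluded_volume_energy(r[k], sig[k], ff$excluded_epsilon,
                               min(ff$ev_cutoff, 2 * sig[k])), 1))
  }
  e_restr <- 0
  if (any(b$anchored)) {
    dx <- xyz[b$anchored, , drop = FALSE] - ref[b$anchored, , drop = FALSE]
    e_restr <- sum(0.5 * ff$restraint_k * rowSums(dx^2))
  }
  e_teth <- 0
  if (nrow(model$tethers) > 0) {
    r <- pair_r(model$tethers, xyz)
    ext <- pmax(0, r - ff$tether_r0)   # slack flat-bottom linker
    e_teth <- sum(0.5 * ff$tether_k * ext^2)
  }
  out <- c(bonded = e_bond, angle = e_angle, native = e_native,
           electrostatic = e_elec, excluded = e_ev,
           restraint = e_restr, tether = e_teth)
  c(out, total = sum(out))
}

# Angle triples (i, j, k) along each flexible (tail) chain.
chain_angles <- function(model) {
  b <- model$beads
  out <- list()
  for (ch in unique(b$chain_id[b$group == "tail"])) {
    ids <- b$bead_id[b$chain_id == ch]
    n <- length(ids)
    if (n >= 3)
      out[[ch]] <- data.frame(i = ids[1:(n - 2)], j = ids[2:(n - 1)],
                              k = ids[3:n])
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), k = integer()))
  do.call(rbind, out)
}

bead_angle <- function(xyz, i, j, k) {
  v1 <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  v2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, cosang)))
}

# Nonbonded candidate pair list (row indices into model$beads):
# excludes pairs within one rigid (fully anchored, non-tail) unit, pairs
# where both beads are anchored, bonded 1-2 and 1-3 neighbours, and
# native-contact pairs from excluded volume (column ev = FALSE keeps
# their electrostatics).
nonbonded_pairs <- function(model) {
  b <- model$beads
  n <- nrow(b)
  if (n < 2)
    return(data.frame(i = integer(), j = integer(), ev = logical()))
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  keep <- !(b$anchored[i] & b$anchored[j]) & (b$chain_id[i] != b$chain_id[j])
  # intra-chain non-neighbour pairs on flexible chains are kept
  same <- b$chain_id[i] == b$chain_id[j]
  sep <- abs(b$residue_index[i] - b$residue_index[j])
  keep <- keep | (same & sep > 2 & !(b$anchored[i] & b$anchored[j]))
  i <- i[keep]; j <- j[keep]
  ev <- rep(TRUE, length(i))
  nc <- model$native_contacts
  if (nrow(nc) > 0) {
    pk <- paste(pmin(b$bead_id[i], b$bead_id[j]),
                pmax(b$bead_id[i], b$bead_id[j]))
    nk <- paste(pmin(nc$i, nc$j), pmax(nc$i, nc$j))
    ev[pk %in% nk] <- FALSE
  }
  data.frame(i = i, j = j, ev = ev)
}


#' Per-bead excluded-volume radius parameter
#'
#' Bulky aromatic residues (TYR, TRP, PHE) take
#' `ff$excluded_sigma_large`; all other residues `ff$excluded_sigma`.
#' Pairs interact with the arithmetic mean of their two values.
#'
#' @param residue_name 3-letter codes.
#' @param ff a [force_field()].
#' @return numeric vector, nm.
#' @export
bead_ev_sigma <- function(residue_name, ff) {
  ifelse(residue_name %in% c("TYR", "TRP", "PHE"),
         ff$excluded_sigma_large, ff$excluded_sigma)
}
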