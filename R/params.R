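#' Simulation parameters
#'
#' Physical conditions and protocol of a Langevin run.  Defaults are the
#' full-protocol conditions: 300 K, relative dielectric 78, ionic
#' strength 0.1 M, friction 2.0 (engine units), 3e7 steps with the first
#' 5e6 excluded as burn-in.  Desk-scale campaigns use
#' [campaign_params()].
#'
#' Engine units: length nm, energy kcal/mol, bead mass `mass` engine mass
#' units, time in engine time units (the friction coefficient is a
#' velocity damping rate per time unit).
#'
#' @param temperature K.
#' @param dielectric relative permittivity of the implicit solvent.
#' @param ionic_strength mol/L.
#' @param friction damping rate, 1/time unit.
#' @param n_steps total MD steps.
#' @param burn_in_steps steps excluded from analysis.
#' @param timestep engine time units.
#' @param seed integer RNG seed (counter-seeded Mersenne Twister in the
#'   engine; the stream is part of the reproducibility contract).
#' @param output_stride steps between saved frames.
#' @param mass per-bead mass, engine units.
#' @param box_bound nm; any |coordinate| beyond this aborts the run
#'   (`NULL` = 10x the initial system extent).
#' @param minimize_steps iterations of displacement-capped steepest
#'   descent run before dynamics to relax steric clashes of the built
#'   geometry (0 disables).
#' @return object of class `sim_params`.
#' @export
sim_params <- function(temperature = 300, dielectric = 78,
                       ionic_strength = 0.1, friction = 2.0,
                       n_steps = 3e7, burn_in_steps = 5e6,
                       timestep = 0.2, seed = 1, output_stride = 500,
                       mass = 100, box_bound = NULL,
                       minimize_steps = 500) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (dielectric <= 0) stop("dielectric must be > 0")
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  if (n_steps <= burn_in_steps || burn_in_steps < 0)
    stop("need n_steps > burn_in_steps >= 0")
  if (output_stride < 1) stop("output_stride must be >= 1")
  structure(list(temperature = temperature, dielectric = dielectric,
                 ionic_strength = ionic_strength, friction = friction,
                 n_steps = as.double(n_steps),
                 burn_in_steps = as.double(burn_in_steps),
                 timestep = timestep, seed = as.integer(seed),
                 output_stride = as.integer(output_stride),
                 mass = mass, box_bound = box_bound,
                 minimize_steps = as.double(minimize_steps)),
            class = "sim_params")
}

#' Desk-scale campaign parameters
#'
#' The packaged toy campaign runs 1e5 steps per trajectory with the same
#' 1/6 burn-in fraction as the full protocol (5e6 of 3e7).
#' @param n_steps,seed,... passed to [sim_params()].
#' @return a [sim_params()].
#' @export
campaign_params <- function(n_steps = 1e5, seed = 1, ...) {
  sim_params(n_steps = n_steps, burn_in_steps = round(n_steps / 6),
             seed = seed, output_stride = 100, ...)
}

#' Bjerrum length
#'
#' Distance at which two unit charges interact with thermal energy:
#' lB = e^2 / (4 pi eps0 eps kB T).
#' @param temperature K.
#' @param dielectric relative permittivity.
#' @return nm.
#' @export
bjerrum_length <- function(temperature = 300, dielectric = 78) {
  (.e_C^2 / (4 * pi * .eps0 * dielectric * .kB_J * temperature)) * 1e9
}

#' Debye screening length
#'
#' lD = sqrt(eps eps0 kB T / (2 NA e^2 I)) with I in mol/L.  At 0.1 M,
#' 300 K, eps = 78 this is about 0.96 nm.
#' @param ionic_strength mol/L (> 0).
#' @param temperature K.
#' @param dielectric relative permittivity.
#' @return nm.
#' @export
debye_length <- function(ionic_strength = 0.1, temperature = 300,
                         dielectric = 78) {
  if (ionic_strength <= 0) stop("ionic_strength must be > 0")
  i_m3 <- ionic_strength * 1000 * .NA_mol   # ions / m^3 (1:1 salt)
  sqrt(dielectric * .eps0 * .kB_J * temperature /
         (2 * i_m3 * .e_C^2)) * 1e9
}

#' Force-field parameters
#'
#' Simplified uniform-epsilon structure-based force field: 12-10 Go native
#' contacts, harmonic bonds/angles at their built rest geometry, purely
#' repulsive shifted r^-12 excluded volume, Debye-Hueckel electrostatics,
#' harmonic positional restraints on anchored beads, and a soft harmonic
#' tether between the two motor heads.  The derived electrostatic lengths
#' (`bjerrum_length`, `debye_length`) are filled in from `params`.
#'
#' @param go_epsilon kcal/mol per native contact (uniform default; motor
#'   internal rigidity contacts carry their own epsilon).
#' @param excluded_sigma nm (default bead diameter parameter).
#' @param excluded_sigma_large nm for bulky aromatic residues (TYR, TRP,
#'   PHE); the larger radius lets the terminal tyrosine cap sterically
#'   shield the tail's C-terminal carboxylate, the shielding that
#'   detyrosination removes.
#' @param excluded_epsilon kcal/mol.
#' @param ev_cutoff nm; pairs additionally cut off at twice their mixed
#'   sigma, with the repulsion shifted to be continuous there.
#' @param bond_k kcal/mol/nm^2.
#' @param angle_k kcal/mol/rad^2 (tail chains only).
#' @param tether_k kcal/mol/nm^2 beyond the slack length (flat-bottom linker).
#' @param tether_r0 nm.
#' @param restraint_k kcal/mol/nm^2 pinning anchored beads.
#' @param elec_cutoff nm for the screened Coulomb term.
#' @param params optional [sim_params()] used to fill the derived lengths.
#' @return object of class `force_field`.
#' @export
force_field <- function(go_epsilon = 0.6, excluded_sigma = 0.4,
                        excluded_sigma_large = 0.6,
                        excluded_epsilon = 0.2, ev_cutoff = 1.2,
                        bond_k = 100, angle_k = 2,
                        tether_k = 0.2, tether_r0 = 12,
                        restraint_k = 1000, elec_cutoff = 3.0,
                        params = NULL) {
  stopifnot(go_epsilon >= 0, excluded_epsilon >= 0, bond_k >= 0,
            angle_k >= 0, tether_k >= 0, restraint_k >= 0)
  ff <- structure(list(go_epsilon = go_epsilon,
                       excluded_sigma = excluded_sigma,
                       excluded_sigma_large = excluded_sigma_large,
                       excluded_epsilon = excluded_epsilon,
                       ev_cutoff = ev_cutoff,
                       bond_k = bond_k, angle_k = angle_k,
                       tether_k = tether_k, tether_r0 = tether_r0,
                       restraint_k = restraint_k,
                       elec_cutoff = elec_cutoff,
                       bjerrum_length = NA_real_,
                       debye_length = NA_real_),
                  class = "force_field")
  if (!is.null(params)) ff <- force_field_refill(ff, params)
  ff
}
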