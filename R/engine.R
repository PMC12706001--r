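#' Run one underdamped Langevin trajectory
#'
#' Integrates the assembled system with the BAOAB splitting of underdamped
#' Langevin dynamics.  Anchored beads (tubulin bodies, tail anchor beads,
#' the high-affinity head) are pinned by harmonic restraints of stiffness
#' `ff$restraint_k`.  Frames are emitted every `params$output_stride`
#' steps; the trajectory is a pure function of (system, params, ff, seed):
#' identical inputs give identical output.
#'
#' @param system a [bead_model()] with the motor placed
#'   (see [place_dimer()]); any model works, tracked groups permitting.
#' @param params a [sim_params()].
#' @param ff a [force_field()]; derived electrostatic lengths are filled
#'   from `params` if missing.
#' @param output_full store full bead positions each frame (needed for
#'   contact maps).
#' @param metadata named list merged into the trajectory metadata.
#' @return object of class `cg_trajectory`: `steps`, `com_low` /
#'   `com_high` (center-of-geometry series of the tracked heads, nm),
#'   optionally `full` (frames x beads x 3), `beads` (bead table),
#'   `energy0` (per-term potential at step 0), `metadata`.
#' @export
run_simulation <- function(system, params = sim_params(),
                           ff = force_field(params = params),
                           output_full = FALSE, metadata = list()) {
  if (is.na(ff$bjerrum_length))
    ff <- force_field_refill(ff, params)
  b <- system$beads
  xyz <- coords(system)
  id2row0 <- function(id) match(id, b$bead_id) - 1L
  pair_mat <- function(df) {
    if (nrow(df) == 0) return(matrix(integer(), 0, 2))
    cbind(id2row0(df$i), id2row0(df$j))
  }
  pr <- function(df) {
    if (nrow(df) == 0) return(numeric())
    sqrt(rowSums((xyz[id2row0(df$i) + 1L, , drop = FALSE] -
                    xyz[id2row0(df$j) + 1L, , drop = FALSE])^2))
  }
  ang <- chain_angles(system)
  ang_m <- if (nrow(ang) == 0) matrix(integer(), 0, 3) else
    cbind(id2row0(ang$i), id2row0(ang$j), id2row0(ang$k))
  ang_th0 <- if (nrow(ang) == 0) numeric() else
    bead_angle(xyz, id2row0(ang$i) + 1L, id2row0(ang$j) + 1L,
               id2row0(ang$k) + 1L)
  nc <- system$native_contacts
  nc_eps <- if (nrow(nc) == 0) numeric() else
    ifelse(is.na(nc$eps), ff$go_epsilon, nc$eps)
  np <- nonbonded_pairs(system)
  track_low <- which(b$group == "mtbd_low") - 1L
  track_high <- which(b$group == "mtbd_high") - 1L
  extent <- max(apply(xyz, 2, function(u) diff(range(u))), 1)
  box <- if (is.null(params$box_bound)) max(10 * extent, 100) else params$box_bound
  par <- c(params[c("timestep", "friction", "temperature", "mass",
                    "n_steps", "output_stride", "seed",
                    "minimize_steps")],
           ff[c("bjerrum_length", "debye_length", "elec_cutoff",
                "ev_cutoff", "excluded_sigma", "excluded_epsilon",
                "bond_k", "angle_k", "tether_k", "tether_r0",
                "restraint_k")],
           list(box_bound = box,
                dh_prefactor = dh_prefactor(params$dielectric)))
  sigma_bead <- bead_ev_sigma(b$residue_name, ff)
  if (!is.finite(par$debye_length)) par$debye_length <- 1e6
  res <- .cg_run(xyz, b$charge, sigma_bead, b$anchored,
                 pair_mat(system$bonds), pr(system$bonds),
                 ang_m, ang_th0,
                 pair_mat(nc), if (nrow(nc)) nc$r0 else numeric(), nc_eps,
                 pair_mat(system$tethers),
                 np$i - 1L, np$j - 1L, np$ev,
                 track_low, track_high, par, output_full)
  if (res$error_frame > 0)
    stop("numeric blow-up: position left the box bound at frame ",
         res$error_frame, " (step ", res$steps[res$error_frame], ")")
  meta <- c(list(seed = params$seed, n_steps = params$n_steps,
                 output_stride = params$output_stride,
                 n_rebuilds = res$n_rebuilds,
                 params_digest = params_digest(params, ff)), metadata)
  structure(list(steps = res$steps, com_low = res$com_low,
                 com_high = res$com_high,
                 full = if (output_full) res$full else NULL,
                 beads = b, energy0 = res$energy0,
                 energy_final = res$energy_final,
                 kinetic_final = res$kinetic_final,
                 metadata = meta),
            class = "cg_trajectory")
}

force_field_refill <- function(ff, params) {
  t_len <- if (params$temperature > 0) params$temperature else 300
  ff$bjerrum_length <- bjerrum_length(t_len, params$dielectric)
  ff$debye_length <- if (params$ionic_strength > 0)
    debye_length(params$ionic_strength, t_len, params$dielectric) else Inf
  ff
}

params_digest <- function(params, ff) {
  v <- c(unlist(params[c("temperature", "dielectric", "ionic_strength",
                         "friction", "n_steps", "timestep", "mass")]),
         unlist(ff[setdiff(names(ff), c("bjerrum_length", "debye_length"))]))
  paste0("p", format(sum(v * seq_along(v)), digits = 12))
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", length(x$steps), "frames, seed",
      x$metadata$seed, "\n")
  if (!is.null(x$metadata$tail_state))
    cat("  state:", x$metadata$tail_state, " position:",
        x$metadata$position_id, "\n")
  invisible(x)
}

#' Run the simulation campaign over states, positions and seeds
#'
#' For each tyrosination state the lattice and motor are assembled once;
#' for each initial position (1 backward, 2 lateral, 3 forward) and each
#' of `n_seeds` seeds (`base_seed + enumeration`, no duplicates) one
#' trajectory is run.  The full protocol is 20 seeds x 3 positions = 60
#' simulations per tubulin modification state; the desk-scale default is
#' 10 seeds at 1e5 steps.  Contact counts between the mobile head and all
#' tubulin beads (1.0 nm cutoff, post-burn-in frames) are accumulated per
#' state while the full frames are in memory, so only light
#' center-of-geometry series are retained per trajectory.  Failed runs
#' are recorded in the manifest and the campaign continues.
#'
#' @param states character subset of `c("Y", "dY")`.
#' @param positions integer subset of 1:3.
#' @param n_seeds trajectories per (state, position).
#' @param params a [sim_params()] (e.g. [campaign_params()]).
#' @param ff a [force_field()].
#' @param spec a [lattice_spec()]; tail_state is overridden per campaign
#'   state.
#' @param motor a [gen_toy_motor()] result.
#' @param base_seed integer; run seeds are `base_seed + 0:(n-1)`.
#' @param contact_cutoff nm for the accumulated contact maps.
#' @param accumulate_contacts logical; disable to save time when only
#'   occupancy is needed.
#' @return object of class `cg_campaign`: `trajectories` (list of
#'   `cg_trajectory` without full frames), `manifest` (data.frame),
#'   `contacts` (per-state [contact_map] accumulators), `grid`, `spec`.
#' @export
run_campaign <- function(states = c("Y", "dY"), positions = 1:3,
                         n_seeds = 10,
                         params = campaign_params(),
                         ff = force_field(params = params),
                         spec = lattice_spec(beads_per_monomer = 8),
                         motor = gen_toy_motor(),
                         base_seed = 1,
                         contact_cutoff = 1.0,
                         accumulate_contacts = TRUE) {
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  ff <- force_field_refill(ff, params)
  grid <- default_grid(spec)
  trajs <- list()
  manifest <- list()
  contacts <- list()
  counter <- 0L
  for (state in states) {
    sp <- spec
    sp$tail_state <- rep(state, sp$n_pf * sp$n_dimers_per_pf)
    lattice <- build_lattice(sp)
    acc <- NULL
    for (pos in positions) {
      system <- place_dimer(lattice, motor, placement_spec(pos), grid)
      for (s in seq_len(n_seeds)) {
        seed <- base_seed + counter
        counter <- counter + 1L
        p <- params
        p$seed <- as.integer(seed)
        tr <- tryCatch(
          run_simulation(system, p, ff, output_full = accumulate_contacts,
                         metadata = list(tail_state = state,
                                         position_id = pos)),
          error = function(e) e)
        ok <- inherits(tr, "cg_trajectory")
        manifest[[length(manifest) + 1L]] <- data.frame(
          state = state, position_id = pos, seed = seed, ok = ok,
          message = if (ok) "" else conditionMessage(tr))
        if (!ok) next
        if (accumulate_contacts) {
          cm <- contact_map(tr,
                            mtbd_selection = mtbd_bead_ids(tr),
                            tubulin_selection = tubulin_bead_ids(tr),
                            cutoff = contact_cutoff,
                            burn_in = params$burn_in_steps)
          acc <- if (is.null(acc)) cm else add_contact_maps(acc, cm)
          tr$full <- NULL
        }
        trajs[[length(trajs) + 1L]] <- tr
      }
    }
    if (accumulate_contacts) contacts[[state]] <- acc
  }
  structure(list(trajectories = trajs,
                 manifest = do.call(rbind, manifest),
                 contacts = contacts, grid = grid, spec = spec,
                 params = params, ff = ff, base_seed = base_seed),
            class = "cg_campaign")
}

mtbd_bead_ids <- function(traj) traj$beads$bead_id[traj$beads$group == "mtbd_low"]
tubulin_bead_ids <- function(traj)
  traj$beads$bead_id[traj$beads$group %in%
                       c("alpha_tubulin", "beta_tubulin", "tail")]

#' @export
print.cg_campaign <- function(x, ...) {
  m <- x$manifest
  cat("cg_campaign:", nrow(m), "runs (", sum(m$ok), "ok ) over states {",
      paste(unique(m$state), collapse = ", "), "}\n")
  invisible(x)
}
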