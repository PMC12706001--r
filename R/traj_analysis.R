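#' Assign a center-of-geometry position to a binding site or OVERFLOW
#'
#' The capture region is the 3x3 grid bounding rectangle extended by half
#' a site spacing per axis (so each site's cell is its Voronoi cell
#' clipped to the rectangle), together with a detachment height bound
#' above the lattice surface.  Inside the region the nearest site index
#' is returned, ties broken toward the lower index; outside (or above the
#' height bound) the assignment is OVERFLOW, which covers both lateral
#' escape from the 3x3 area and detachment from the lattice.
#'
#' @param com 3-vector or n x 3 matrix of positions, nm.
#' @param grid a [site_grid()].
#' @return data.frame with columns `row`, `col` (0..2, center = (1,1))
#'   and `overflow` (logical); for OVERFLOW rows `row`/`col` are `NA`.
#' @export
assign_site <- function(com, grid) {
  if (is.null(dim(com))) com <- matrix(com, nrow = 1)
  rel <- sweep(com, 2, grid$center)
  u <- as.vector(rel %*% grid$axial_direction)
  v <- as.vector(rel %*% grid$lateral_direction)
  h <- as.vector(com %*% grid$normal) - grid$surface_z
  inside <- abs(u) <= 1.5 * grid$axial_spacing &
    abs(v) <= 1.5 * grid$lateral_spacing &
    h <= grid$detach_height
  # nearest center along each axis; exact midpoints go to the lower index
  row <- pmin(1, pmax(-1, ceiling(u / grid$axial_spacing - 0.5))) + 1
  col <- pmin(1, pmax(-1, ceiling(v / grid$lateral_spacing - 0.5))) + 1
  data.frame(row = ifelse(inside, row, NA_integer_),
             col = ifelse(inside, col, NA_integer_),
             overflow = !inside)
}

#' Binding-site occupancy heatmaps with burn-in exclusion
#'
#' Per-frame site assignment of the low-affinity head center of geometry
#' for frames after `burn_in` steps.  Overflow is trajectory-level and
#' absorbing: once a trajectory leaves the capture region its remaining
#' frames are excluded from the grid mass.  Grids are normalized over the
#' retained frames, per initial position and summed over positions;
#' overflow is reported separately as a percentage of trajectories.
#'
#' @param trajs list of `cg_trajectory` (or a `cg_campaign`).
#' @param grid a [site_grid()].
#' @param burn_in steps excluded from the start of each trajectory.
#' @return object of class `occupancy_result`: `per_position_grid`
#'   (named list of 3x3 matrices), `summed_grid`, `overflow_percent`,
#'   `n_trajectories`, `frames_used`, `total_frames`.
#' @export
occupancy <- function(trajs, grid, burn_in = 0) {
  if (inherits(trajs, "cg_campaign")) trajs <- trajs$trajectories
  if (length(trajs) == 0) stop("no trajectories")
  digests <- vapply(trajs, function(t)
    t$metadata$params_digest %||% "", "")
  if (length(unique(digests)) > 1)
    warning("trajectories have differing parameter digests")
  counts <- list()
  overflow_n <- 0L
  used <- 0L
  total <- 0L
  kept_trajs <- 0L
  for (tr in trajs) {
    keep <- tr$steps > burn_in
    total <- total + length(tr$steps)
    if (!any(keep)) {
      warning("trajectory shorter than burn-in excluded")
      next
    }
    kept_trajs <- kept_trajs + 1L
    a <- assign_site(tr$com_low[keep, , drop = FALSE], grid)
    first_of <- which(a$overflow)[1]
    if (!is.na(first_of)) {
      overflow_n <- overflow_n + 1L
      a <- a[seq_len(first_of - 1L), , drop = FALSE]
    }
    used <- used + nrow(a)
    pos <- as.character(tr$metadata$position_id %||% 0)
    g <- counts[[pos]]
    if (is.null(g)) g <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
    if (nrow(a) > 0)
      for (k in seq_len(nrow(a)))
        g[a$row[k] + 1L, a$col[k] + 1L] <- g[a$row[k] + 1L, a$col[k] + 1L] + 1
    counts[[pos]] <- g
  }
  if (kept_trajs == 0) stop("all trajectories shorter than burn-in")
  summed <- Reduce(`+`, counts)
  norm <- function(g) if (sum(g) > 0) g / sum(g) else g
  structure(list(per_position_grid = lapply(counts, norm),
                 summed_grid = norm(summed),
                 overflow_percent = 100 * overflow_n / kept_trajs,
                 n_trajectories = kept_trajs,
                 frames_used = used, total_frames = total),
            class = "occupancy_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occupancy_result <- function(x, ...) {
  cat("occupancy over", x$n_trajectories, "trajectories,",
      x$frames_used, "frames retained\n")
  print(round(x$summed_grid, 3))
  cat("overflow:", sprintf("%.2f%%", x$overflow_percent), "\n")
  invisible(x)
}

#' Overflow proportion with bootstrap confidence interval
#'
#' Percentage of trajectories in which the mobile head detaches from the
#' lattice or moves outside the 3x3 site region in any post-burn-in
#' frame.  The CI resamples trajectories with replacement.
#'
#' @param trajs list of `cg_trajectory` (or a `cg_campaign`).
#' @param grid a [site_grid()].
#' @param burn_in steps excluded from the start.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param boot_seed seed for the resampling.
#' @return list: `percent`, `n`, `n_overflow`, `ci` (two percentages),
#'   `flags` (per-trajectory logical).
#' @export
overflow_proportion <- function(trajs, grid, burn_in = 0, n_boot = 2000,
                                conf = 0.95, boot_seed = 1) {
  if (inherits(trajs, "cg_campaign")) trajs <- trajs$trajectories
  if (length(trajs) == 0) stop("no trajectories")
  flags <- vapply(trajs, function(tr) {
    keep <- tr$steps > burn_in
    any(assign_site(tr$com_low[keep, , drop = FALSE], grid)$overflow)
  }, TRUE)
  n <- length(flags)
  set.seed(boot_seed)
  boots <- vapply(seq_len(n_boot), function(k)
    100 * mean(sample(flags, n, replace = TRUE)), 1)
  list(percent = 100 * mean(flags), n = n, n_overflow = sum(flags),
       ci = unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2))),
       flags = flags)
}

#' Residue contact map of a full-bead trajectory
#'
#' Per frame, a residue (bead) pair between the mobile head and the
#' tubulin selection counts one contact event when its distance is at or
#' under `cutoff` (1.0 nm by default); events are accumulated over the
#' retained frames.
#'
#' @param traj a `cg_trajectory` run with `output_full = TRUE`.
#' @param mtbd_selection bead_ids of the head rows.
#' @param tubulin_selection bead_ids of the tubulin columns.
#' @param cutoff nm.
#' @param burn_in steps excluded from the start.
#' @return object of class `contact_map`: integer `counts` (rows =
#'   head labels, cols = tubulin labels), `n_frames`, `cutoff`.
#' @export
contact_map <- function(traj, mtbd_selection, tubulin_selection,
                        cutoff = 1.0, burn_in = 0) {
  if (is.null(traj$full)) stop("trajectory lacks full bead positions")
  if (length(mtbd_selection) == 0 || length(tubulin_selection) == 0)
    stop("selections must be non-empty")
  b <- traj$beads
  li <- match(mtbd_selection, b$bead_id)
  ti <- match(tubulin_selection, b$bead_id)
  lab <- function(rows) sprintf("%s:%s%d", b$chain_id[rows],
                                b$residue_name[rows], b$residue_index[rows])
  frames <- which(traj$steps > burn_in)
  counts <- matrix(0L, length(li), length(ti),
                   dimnames = list(lab(li), lab(ti)))
  for (f in frames) {
    xa <- traj$full[f, li, , drop = FALSE]; dim(xa) <- c(length(li), 3)
    xb <- traj$full[f, ti, , drop = FALSE]; dim(xb) <- c(length(ti), 3)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    counts <- counts + (d2 <= cutoff^2)
  }
  structure(list(counts = counts, n_frames = length(frames),
                 cutoff = cutoff),
            class = "contact_map")
}

#' Combine contact maps accumulated over runs
#' @param a,b `contact_map` objects with identical labels and cutoff.
#' @return the summed `contact_map`.
#' @export
add_contact_maps <- function(a, b) {
  if (!identical(dimnames(a$counts), dimnames(b$counts)))
    stop("contact map label mismatch")
  a$counts <- a$counts + b$counts
  a$n_frames <- a$n_frames + b$n_frames
  a
}

#' Differential contact map (detyrosinated minus tyrosinated)
#'
#' Contact counts are normalized to per-frame frequencies before
#' subtraction so campaigns of different lengths compare fairly:
#' `delta = counts(dY)/frames(dY) - counts(Y)/frames(Y)`.  Positive cells
#' are contacts formed preferentially upon detyrosination.  Column labels
#' present only in the tyrosinated map and naming a terminal TYR (absent
#' by construction in the detyrosinated lattice) are dropped; any other
#' label mismatch is an error.
#'
#' @param map_dY,map_Y `contact_map` objects.
#' @return object of class `diff_contact_map` with matrix `delta`.
#' @export
diff_contact_map <- function(map_dY, map_Y) {
  ra <- rownames(map_dY$counts); rb <- rownames(map_Y$counts)
  ca <- colnames(map_dY$counts); cb <- colnames(map_Y$counts)
  if (!identical(ra, rb)) stop("row label mismatch between maps")
  only <- union(setdiff(ca, cb), setdiff(cb, ca))
  tyr <- grepl(":TYR", only)
  if (any(!tyr))
    stop("column label mismatch beyond terminal TYR: ",
         paste(only[!tyr], collapse = ", "))
  common <- intersect(ca, cb)
  delta <- map_dY$counts[, common, drop = FALSE] / map_dY$n_frames -
    map_Y$counts[, common, drop = FALSE] / map_Y$n_frames
  structure(list(delta = delta,
                 n_frames_dY = map_dY$n_frames,
                 n_frames_Y = map_Y$n_frames,
                 dropped_cols = only[tyr]),
            class = "diff_contact_map")
}

#' Fraction of frames in which the mobile head leads
#'
#' Fraction of post-burn-in frames where the low-affinity head's
#' center-of-geometry coordinate along `axis` (the minus-end direction,
#' i.e. the direction of dynein movement) exceeds the high-affinity
#' head's.
#'
#' @param traj a `cg_trajectory` with both head series.
#' @param axis unit 3-vector toward the minus end.
#' @param burn_in steps excluded from the start.
#' @return numeric fraction in 0..1.
#' @export
leading_head_fraction <- function(traj, axis = c(1, 0, 0), burn_in = 0) {
  if (is.null(traj$com_high) || all(traj$com_high == 0))
    stop("missing high-affinity head series")
  axis <- axis / sqrt(sum(axis^2))
  keep <- traj$steps > burn_in
  lo <- as.vector(traj$com_low[keep, , drop = FALSE] %*% axis)
  hi <- as.vector(traj$com_high[keep, , drop = FALSE] %*% axis)
  mean(lo > hi)
}
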