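make_grid <- function() site_grid(center = c(0, 0, 3), axial_spacing = 8.2,
                                  lateral_spacing = 5.2, surface_z = 1.6,
                                  detach_height = 6)

test_that("assign_site returns the nearest site or OVERFLOW", {
  g <- make_grid()
  expect_equal(unlist(assign_site(c(0, 0, 3), g)[, 1:2]),
               c(row = 1, col = 1))
  expect_equal(unlist(assign_site(c(8.2, -5.2, 3), g)[, 1:2]),
               c(row = 2, col = 0))
  expect_true(assign_site(c(0, 52, 3), g)$overflow)      # 10x lateral
  expect_true(assign_site(c(0, 0, 3 + 60), g)$overflow)  # detached
  # exact midpoint between sites breaks toward the lower index
  mid <- assign_site(c(8.2 / 2, 0, 3), g)
  expect_equal(mid$row, 1)
})

test_that("assign_site equals a brute-force nearest-center scan", {
  g <- make_grid()
  set.seed(1)
  pts <- cbind(runif(1000, -20, 20), runif(1000, -15, 15),
               runif(1000, 0, 12))
  got <- assign_site(pts, g)
  for (k in seq_len(1000)) {
    p <- pts[k, ]
    u <- p[1]; v <- p[2]; h <- p[3] - g$surface_z
    if (abs(u) > 1.5 * 8.2 || abs(v) > 1.5 * 5.2 || h > 6) {
      expect_true(got$overflow[k])
    } else {
      d <- sqrt((g$site_centers[, 1] - p[1])^2 +
                  (g$site_centers[, 2] - p[2])^2)
      best <- which.min(d + 1e-9 * (g$row * 3 + g$col))  # lower-index ties
      expect_false(got$overflow[k])
      expect_equal(c(got$row[k], got$col[k]),
                   c(g$row[best], g$col[best]))
    }
  }
})

test_that("occupancy puts all mass on the grid for walks that stay in", {
  g <- make_grid()
  stat <- fake_traj(matrix(rep(c(0, 0, 3), 10), ncol = 3, byrow = TRUE))
  occ <- occupancy(list(stat), g)
  expect_equal(occ$summed_grid["1", "1"], 1)
  expect_equal(sum(occ$summed_grid), 1)
  expect_equal(occ$overflow_percent, 0)
  # three frames visiting distinct sites: 1/3 each
  tr3 <- fake_traj(rbind(c(0, 0, 3), c(0, -5.2, 3), c(-8.2, 0, 3)))
  occ3 <- occupancy(list(tr3), g)
  expect_equal(occ3$summed_grid["1", "1"], 1 / 3)
  expect_equal(occ3$summed_grid["1", "0"], 1 / 3)
  expect_equal(occ3$summed_grid["0", "1"], 1 / 3)
})

test_that("burn-in exclusion retains 5/6 of frames for the full protocol", {
  # 3e7 steps, burn-in 5e6, uniform stride
  stride <- 5e5
  steps <- seq(stride, 3e7, by = stride)
  com <- matrix(rep(c(0, 0, 3), length(steps)), ncol = 3, byrow = TRUE)
  tr <- fake_traj(com, stride = stride)
  occ <- occupancy(list(tr), make_grid(), burn_in = 5e6)
  expect_equal(occ$frames_used / occ$total_frames, 5 / 6)
})

test_that("overflow is trajectory-level, absorbing, and bootstrapped", {
  g <- make_grid()
  stay <- fake_traj(matrix(rep(c(0, 0, 3), 20), ncol = 3, byrow = TRUE))
  # escapes at frame 10 and returns: still one overflow trajectory,
  # frames after first exit never contribute grid mass
  com <- matrix(rep(c(0, 0, 3), 20), ncol = 3, byrow = TRUE)
  com[10, ] <- c(40, 0, 3)
  esc <- fake_traj(com)
  trajs <- c(replicate(17, stay, simplify = FALSE),
             replicate(3, esc, simplify = FALSE))
  ov <- overflow_proportion(trajs, g)
  expect_equal(ov$percent, 15)
  expect_equal(ov$n_overflow, 3)
  expect_true(ov$ci[1] <= 15 && 15 <= ov$ci[2])
  occ <- occupancy(trajs, g)
  expect_equal(occ$overflow_percent, 15)
  expect_equal(occ$frames_used, 17 * 20 + 3 * 9)
  expect_error(overflow_proportion(list(), g), "no trajectories")
  # all stationary: 0%
  expect_equal(overflow_proportion(list(stay), g)$percent, 0)
})

test_that("overflow grows as the capture region shrinks", {
  set.seed(9)
  walks <- gen_random_walk_trajectories(n = 60, n_frames = 150,
                                        step_sd = 0.8, seed = 4,
                                        start = c(0, 0, 3))
  pct <- vapply(c(1.4, 1.0, 0.6), function(scale) {
    g <- site_grid(center = c(0, 0, 3), axial_spacing = 8.2 * scale,
                   lateral_spacing = 5.2 * scale, surface_z = 1.6,
                   detach_height = 1000)
    overflow_proportion(walks, g)$percent
  }, 1)
  expect_true(all(diff(pct) >= 0))
})

test_that("overflow matches the Markov-chain absorption oracle", {
  # discrete walk on the 3x3 sites: each frame move one site up/down/
  # left/right with probability 1/4 each; leaving the grid absorbs.
  n_frames <- 12; n_walks <- 500
  # oracle: transition-matrix absorption probability
  P <- matrix(0, 10, 10)   # states 1..9 = (row, col), 10 = absorbed
  id <- function(r, c) 3 * r + c + 1
  for (r in 0:2) for (c in 0:2) {
    for (mv in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r2 <- r + mv[1]; c2 <- c + mv[2]
      to <- if (r2 < 0 || r2 > 2 || c2 < 0 || c2 > 2) 10 else id(r2, c2)
      P[id(r, c), to] <- P[id(r, c), to] + 0.25
    }
  }
  P[10, 10] <- 1
  v <- rep(0, 10); v[id(1, 1)] <- 1
  for (t in seq_len(n_frames)) v <- v %*% P
  p_abs <- v[10]
  # simulate the same walk as trajectories
  g <- make_grid()
  set.seed(31)
  trajs <- lapply(seq_len(n_walks), function(k) {
    rc <- c(1, 1)
    com <- matrix(NA_real_, n_frames, 3)
    for (t in seq_len(n_frames)) {
      mv <- switch(sample(4, 1), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
      rc <- rc + mv
      com[t, ] <- if (any(rc < 0) || any(rc > 2)) c(100, 100, 3) else
        c((rc[1] - 1) * 8.2, (rc[2] - 1) * 5.2, 3)
      if (any(rc < 0) || any(rc > 2)) {
        if (t < n_frames) com[(t + 1):n_frames, ] <-
            matrix(c(100, 100, 3), n_frames - t, 3, byrow = TRUE)
        break
      }
    }
    fake_traj(com)
  })
  got <- overflow_proportion(trajs, g)$percent / 100
  ci <- p_abs + c(-1, 1) * 3 * sqrt(p_abs * (1 - p_abs) / n_walks)
  expect_gt(got, ci[1])
  expect_lt(got, ci[2])
})

test_that("contact_map counts pairs within the cutoff per frame", {
  # two beads held at 0.9 nm for 10 frames -> count 10; far pair -> 0
  beads <- data.frame(bead_id = 1:3, chain_id = c("ML", "A_p1_d1", "A_p1_d1"),
                      residue_index = c(1, 1, 2),
                      residue_name = c("LYS", "GLU", "GLY"),
                      x = 0, y = 0, z = 0, charge = 0,
                      group = c("mtbd_low", "alpha_tubulin", "alpha_tubulin"),
                      anchored = FALSE)
  full <- array(0, c(10, 3, 3))
  full[, 2, 1] <- 0.9     # bead 2 at x = 0.9
  full[, 3, 1] <- 5       # bead 3 far away
  tr <- structure(list(steps = 1:10, com_low = matrix(0, 10, 3),
                       com_high = matrix(0, 10, 3), full = full,
                       beads = beads, metadata = list(seed = 0)),
                  class = "cg_trajectory")
  cm <- contact_map(tr, mtbd_selection = 1, tubulin_selection = 2:3)
  expect_equal(unname(cm$counts[1, 1]), 10)
  expect_equal(unname(cm$counts[1, 2]), 0)
  expect_equal(cm$n_frames, 10)
  expect_error(contact_map(tr, integer(), 2:3), "non-empty")
})

test_that("contact_map equals brute force and ignores frame order", {
  set.seed(21)
  nb <- 6; nf <- 5
  beads <- data.frame(bead_id = 1:nb, chain_id = rep(c("ML", "T_p1"), each = 3),
                      residue_index = rep(1:3, 2),
                      residue_name = "GLY", x = 0, y = 0, z = 0,
                      charge = 0,
                      group = rep(c("mtbd_low", "tail"), each = 3),
                      anchored = FALSE)
  full <- array(runif(nf * nb * 3, 0, 2), c(nf, nb, 3))
  mk <- function(fr) structure(
    list(steps = seq_len(dim(fr)[1]), com_low = matrix(0, dim(fr)[1], 3),
         com_high = matrix(0, dim(fr)[1], 3), full = fr, beads = beads,
         metadata = list(seed = 0)), class = "cg_trajectory")
  cm <- contact_map(mk(full), 1:3, 4:6, cutoff = 1.0)
  brute <- matrix(0, 3, 3)
  for (f in 1:nf) for (i in 1:3) for (j in 4:6)
    brute[i, j - 3] <- brute[i, j - 3] +
      (sqrt(sum((full[f, i, ] - full[f, j, ])^2)) <= 1.0)
  expect_equal(unname(cm$counts), brute)
  expect_true(all(cm$counts <= cm$n_frames))
  # permutation of frames leaves counts unchanged
  cm_rev <- contact_map(mk(full[nf:1, , , drop = FALSE]), 1:3, 4:6)
  expect_equal(cm_rev$counts, cm$counts)
})

test_that("diff_contact_map subtracts normalized frequencies", {
  mk <- function(counts, nf, cols) structure(
    list(counts = matrix(counts, 2, 2,
                         dimnames = list(c("ML:LYS1", "ML:GLY2"), cols)),
         n_frames = nf, cutoff = 1), class = "contact_map")
  a <- mk(c(4, 0, 2, 6), 10, c("T:GLU1", "T:GLU2"))
  expect_equal(unname(diff_contact_map(a, a)$delta),
               matrix(0, 2, 2))
  b <- mk(c(1, 1, 1, 1), 5, c("T:GLU1", "T:GLU2"))
  d1 <- diff_contact_map(a, b)$delta
  d2 <- diff_contact_map(b, a)$delta
  expect_equal(d1, -d2)
  expect_equal(unname(d1[1, 1]), 4 / 10 - 1 / 5)
  # terminal TYR columns present only in the Y map are dropped
  y <- mk(c(1, 1, 1, 1), 5, c("T:GLU1", "T:TYR21"))
  dy <- mk(c(2, 2, 2, 2), 5, c("T:GLU1", "T:GLU20"))
  expect_error(diff_contact_map(dy, y), "beyond terminal TYR")
  y2 <- mk(c(1, 1, 1, 1), 5, c("T:GLU1", "T:TYR21"))
  dy2 <- mk(c(2, 2, 2, 2), 5, c("T:GLU1", "T:GLU2"))
  # only the TYR mismatch case is tolerated
  dy3 <- structure(list(counts = y2$counts[, 1, drop = FALSE],
                        n_frames = 5, cutoff = 1), class = "contact_map")
  res <- diff_contact_map(dy3, y2)
  expect_equal(colnames(res$delta), "T:GLU1")
  expect_equal(res$dropped_cols, "T:TYR21")
})

test_that("leading_head_fraction is the order statistic along the axis", {
  ahead <- fake_traj(cbind(2:11, 0, 0), com_high = cbind(rep(1, 10), 0, 0))
  expect_equal(leading_head_fraction(ahead), 1)
  four <- fake_traj(cbind(c(2, 2, 0, 2), 0, 0),
                    com_high = cbind(rep(1, 4), 0, 0))
  expect_equal(leading_head_fraction(four), 0.75)
  # symmetric random walk around the fixed head: about 1/2
  walks <- gen_random_walk_trajectories(n = 40, n_frames = 400,
                                        step_sd = 0.5, seed = 8,
                                        start = c(0, 0, 3))
  fr <- mean(vapply(walks, leading_head_fraction, 1))
  expect_equal(fr, 0.5, tolerance = 0.08)
  bad <- ahead; bad$com_high <- NULL
  expect_error(leading_head_fraction(bad), "missing high-affinity")
})
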