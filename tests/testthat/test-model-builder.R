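test_that("build_lattice produces the documented composition", {
  spec <- tiny_spec()
  m <- build_lattice(spec)
  b <- m$beads
  # 4 PF x 3 dimers: 24 monomers, 12 tail chains
  expect_equal(sum(startsWith(unique(b$chain_id), "A_")), 12)
  expect_equal(sum(startsWith(unique(b$chain_id), "B_")), 12)
  expect_equal(sum(startsWith(unique(b$chain_id), "T_")), 12)
  tail_len <- nchar(spec$tail_sequence)
  expect_equal(nrow(b), 4 * 3 * (8 * 2 + tail_len))
  # minimal lattice
  m1 <- build_lattice(tiny_spec(n_pf = 1, n_dimers_per_pf = 1))
  expect_equal(sum(m1$beads$group != "tail"), 2 * 8)
  expect_equal(length(unique(m1$beads$chain_id[m1$beads$group == "tail"])), 1)
})

test_that("lattice geometry matches the spacing parameters", {
  spec <- tiny_spec()
  m <- build_lattice(spec)
  b <- m$beads
  pick <- function(chain, ri) {
    r <- b[b$chain_id == chain & b$residue_index == ri, ]
    c(r$x, r$y, r$z)
  }
  # equivalent beads on adjacent PFs: lateral_spacing apart in y,
  # stagger apart in x
  d <- pick("A_p2_d1", 3) - pick("A_p1_d1", 3)
  expect_equal(abs(d[2]), spec$lateral_spacing, tolerance = 1e-12)
  expect_equal(abs(d[1]), spec$stagger, tolerance = 1e-12)
  # successive dimers along a PF: axial rise apart
  d2 <- pick("A_p1_d2", 5) - pick("A_p1_d1", 5)
  expect_equal(d2[1], spec$axial_rise_per_dimer, tolerance = 1e-12)
  expect_equal(d2[2], 0, tolerance = 1e-12)
  # deterministic: no randomness
  expect_identical(coords(m), coords(build_lattice(spec)))
})

test_that("build_lattice validates its spec", {
  expect_error(lattice_spec(n_pf = 0), "n_pf")
  expect_error(lattice_spec(axial_rise_per_dimer = -1), "> 0")
  expect_error(lattice_spec(tail_sequence = ""), "non-empty")
  expect_error(lattice_spec(tail_state = "X"), "tail_state")
})

test_that("assign_charges implements the stated rules", {
  g5 <- assign_charges(chain_model(5, residue = "GLY"))
  expect_equal(g5$beads$charge, c(0, 0, 0, 0, -1))
  eey <- assign_charges(chain_model(3, residue = c("GLU", "GLU", "TYR")))
  expect_equal(eey$beads$charge, c(-1, -1, -1))
  ee <- assign_charges(chain_model(2, residue = c("GLU", "GLU")))
  expect_equal(ee$beads$charge, c(-1, -2))
  # idempotent
  expect_identical(assign_charges(ee)$beads$charge, ee$beads$charge)
  # unknown residue names the offending bead
  bad <- chain_model(2)
  bad$beads$residue_name[2] <- "XXX"
  expect_error(assign_charges(bad), "bead_id.*2")
  # any tail's total charge is -(count of D/E) - 1
  m <- build_lattice(tiny_spec())
  for (ch in unique(m$beads$chain_id[m$beads$group == "tail"])) {
    tb <- m$beads[m$beads$chain_id == ch, ]
    expect_equal(sum(tb$charge),
                 -sum(tb$residue_name %in% c("ASP", "GLU")) - 1)
  }
})

test_that("set_tyrosination removes the terminal tyrosine and moves the
           carboxylate charge", {
  m <- build_lattice(tiny_spec())
  n0 <- nrow(m$beads)
  dy <- set_tyrosination(m, "dY")
  expect_equal(n0 - nrow(dy$beads), 12)   # one bead per tail
  # terminal bead is now GLU carrying side chain + carboxylate
  for (ch in unique(dy$beads$chain_id[dy$beads$group == "tail"])) {
    tb <- dy$beads[dy$beads$chain_id == ch, ]
    expect_equal(tb$residue_name[nrow(tb)], "GLU")
    expect_equal(tb$charge[nrow(tb)], -2)
  }
  # net tail charge unchanged by detyrosination
  tail_q <- function(mm) sum(mm$beads$charge[mm$beads$group == "tail"])
  expect_equal(tail_q(dy), tail_q(m))
  # dY twice raises; Y on dY warns and is identity
  expect_error(set_tyrosination(dy, "dY"), "not ending in TYR")
  expect_warning(y2 <- set_tyrosination(dy, "Y"), "already detyrosinated")
  expect_identical(y2$beads, dy$beads)
  # Y on Y is a silent identity
  expect_silent(yy <- set_tyrosination(m, "Y"))
  expect_identical(yy$beads, m$beads)
})

test_that("load_structure builds one bead per residue with Go contacts", {
  # 10-residue chain: 10 beads, 9 bonds
  xyz <- cbind(0.38 * (1:10), 0, 0)
  f <- write_tiny_pdb(xyz, tempfile(fileext = ".pdb"))
  m <- load_structure(f)
  expect_equal(nrow(m$beads), 10)
  expect_equal(nrow(m$bonds), 9)
  # round trip of coordinates (PDB stores 3 decimals in Angstrom)
  expect_equal(as.matrix(m$beads[, c("x", "y", "z")]), xyz,
               tolerance = 1e-4, ignore_attr = TRUE)
  # native contacts equal a brute-force all-pairs scan
  set.seed(42)
  coil <- matrix(cumsum(rnorm(60, sd = 0.2)), ncol = 3)
  f2 <- write_tiny_pdb(coil, tempfile(fileext = ".pdb"))
  m2 <- load_structure(f2)
  d <- as.matrix(dist(coil))
  expected <- sum(upper.tri(d) & d <= 0.65 &
                    abs(row(d) - col(d)) >= 4)
  expect_equal(nrow(m2$native_contacts), expected)
  expect_true(all(m2$native_contacts$r0 > 0))
})

test_that("bead model JSON round-trips exactly", {
  m <- place_dimer(build_lattice(tiny_spec(n_pf = 2)), gen_toy_motor(),
                   2, default_grid(tiny_spec(n_pf = 2)))
  f <- tempfile(fileext = ".json")
  write_beads_json(m, f)
  m2 <- read_beads_json(f)
  expect_equal(m2$beads$x, m$beads$x)
  expect_equal(m2$native_contacts$r0, m$native_contacts$r0)
  expect_equal(m2$tethers, m$tethers, ignore_attr = TRUE)
})

test_that("place_dimer realizes the three initial positions", {
  spec <- tiny_spec()
  lat <- build_lattice(spec)
  motor <- gen_toy_motor()
  grid <- default_grid(spec)
  cog <- function(sys, grp)
    center_of_geometry(sys, sys$beads$bead_id[sys$beads$group == grp])
  sys2 <- place_dimer(lat, motor, 2, grid)
  lo <- cog(sys2, "mtbd_low"); hi <- cog(sys2, "mtbd_high")
  # low head sits at the grid center site
  expect_equal(lo, grid$center, tolerance = 1e-9, ignore_attr = TRUE)
  # position 2: zero axial offset, one PF over
  expect_equal(unname(hi[1] - lo[1]), 0, tolerance = 1e-9)
  expect_equal(unname(hi[2] - lo[2]), spec$lateral_spacing,
               tolerance = 1e-9)
  # position 3: high head one site toward the minus end (+axial)
  sys3 <- place_dimer(lat, motor, 3, grid)
  off3 <- cog(sys3, "mtbd_high")[1] - cog(sys3, "mtbd_low")[1]
  expect_equal(unname(off3), spec$axial_rise_per_dimer,
               tolerance = 1e-9)
  # positions 1 and 3 are mirror images under axial reflection
  off1 <- cog(place_dimer(lat, motor, 1, grid), "mtbd_high")[1] - lo[1]
  expect_equal(off1, -off3, tolerance = 1e-9)
  # lattice coordinates are untouched; motor insertion only adds beads
  nlat <- nrow(lat$beads)
  expect_identical(coords(sys2)[seq_len(nlat), ], coords(lat))
  expect_gt(nrow(sys2$beads), nlat)
  # high head is anchored, low head free
  expect_true(all(sys2$beads$anchored[sys2$beads$group == "mtbd_high"]))
  expect_false(any(sys2$beads$anchored[sys2$beads$group == "mtbd_low"]))
  expect_error(placement_spec(4), "position_id")
})

test_that("superpose_rmsd is a proper minimal RMSD", {
  set.seed(7)
  xyz <- matrix(rnorm(30), ncol = 3)
  m <- chain_model(10)
  m$beads[, c("x", "y", "z")] <- xyz
  # identity and rigid-motion invariance
  expect_equal(superpose_rmsd(m, m), 0, tolerance = 1e-9)
  expect_equal(superpose_rmsd(m, apply_motion(m)), 0, tolerance = 1e-7)
  # symmetry and invariance under motion of either argument
  m2 <- chain_model(10)
  m2$beads[, c("x", "y", "z")] <- xyz + matrix(rnorm(30, sd = 0.1), ncol = 3)
  expect_equal(superpose_rmsd(m, m2), superpose_rmsd(m2, m),
               tolerance = 1e-9)
  expect_equal(superpose_rmsd(m, m2),
               superpose_rmsd(apply_motion(m), m2), tolerance = 1e-7)
  # errors
  expect_error(superpose_rmsd(chain_model(2), chain_model(2)), "at least 3")
  expect_error(superpose_rmsd(chain_model(4), chain_model(5)),
               "mismatched")
})

test_that("superpose_rmsd matches a brute-force rotation search on
           4-point toys", {
  set.seed(11)
  p <- matrix(rnorm(12), ncol = 3)
  q <- p + matrix(rnorm(12, sd = 0.3), ncol = 3)
  ma <- chain_model(4); ma$beads[, c("x", "y", "z")] <- p
  mb <- chain_model(4); mb$beads[, c("x", "y", "z")] <- q
  got <- superpose_rmsd(ma, mb)   # Angstrom
  # oracle: dense grid over Euler angles, centered point sets
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  best <- Inf
  gr <- seq(0, 2 * pi, length.out = 60)
  gr2 <- seq(0, pi, length.out = 30)
  for (a in gr) for (be in gr2) for (g in gr) {
    rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cos(be), 0, sin(be), 0, 1, 0, -sin(be), 0, cos(be)), 3, 3)
    rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    r <- rz1 %*% ry %*% rz2
    best <- min(best, sqrt(mean(rowSums((pc %*% t(r) - qc)^2))))
  }
  expect_lte(got, best * 10 + 1e-3)        # Kabsch at least as good
  expect_equal(got, best * 10, tolerance = 2e-2)  # grid resolution limit
})

test_that("superpose_rmsd agrees with an independent reference
           implementation", {
  set.seed(3)
  n <- 25
  p <- matrix(cumsum(rnorm(3 * n, sd = 0.4)), ncol = 3)
  q <- rigid_motion(p) + matrix(rnorm(3 * n, sd = 0.05), ncol = 3)
  ma <- chain_model(n); ma$beads[, c("x", "y", "z")] <- p
  mb <- chain_model(n); mb$beads[, c("x", "y", "z")] <- q
  got_A <- superpose_rmsd(ma, mb)
  ref <- bio3d::rmsd(as.vector(t(p * 10)), as.vector(t(q * 10)),
                     fit = TRUE)
  expect_equal(got_A, ref, tolerance = 1e-3)
})
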