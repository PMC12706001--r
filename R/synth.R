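#' Generate synthetic tomogram doublet annotations with known ground truth
#'
#' Per doublet, head counts on the A- and B-tubule are drawn
#' Poisson(rate * axis_length / 100).  A-tubule heads are paired into
#' dimers (two at a time); each dimer is assigned a configuration class
#' from `config_probs` = P(Configuration 1, 2, 3, other) and its two
#' heads are placed with geometry realizing that class (partner on the
#' right-hand side, axial offset +8 / 0 / -8 nm for classes 1/2/3;
#' laterally coincident for `other`), so [classify_dimers()] recovers the
#' label.  The generating parameters are embedded as the `ground_truth`
#' attribute.
#'
#' @param n_doublets number of doublets.
#' @param axis_length_nm axis length per doublet.
#' @param rate_A,rate_B heads per 100 nm.
#' @param config_probs length-4 probability vector (sums to 1).
#' @param seed integer.
#' @param exact_proportions allocate class counts by largest remainder
#'   instead of sampling (used for fixtures realizing an exact printed
#'   composition).
#' @return list of [tomo_annotation()] with attribute `ground_truth`.
#' @export
gen_tomo_annotations <- function(n_doublets = 24, axis_length_nm = 1000,
                                 rate_A = 3.0, rate_B = 1.0,
                                 config_probs = c(0.163, 0.256, 0.302, 0.279),
                                 seed = 1, exact_proportions = FALSE) {
  if (rate_A < 0 || rate_B < 0) stop("rates must be >= 0")
  if (abs(sum(config_probs) - 1) > 1e-9 || any(config_probs < 0))
    stop("config_probs must be a probability vector summing to 1")
  set.seed(seed)
  classes <- c("1", "2", "3", "other")
  anns <- lapply(seq_len(n_doublets), function(d) {
    nA <- rpois(1, rate_A * axis_length_nm / 100)
    nB <- rpois(1, rate_B * axis_length_nm / 100)
    axis <- cbind(x = seq(0, axis_length_nm, length.out = 11), y = 0, z = 0)
    n_dimers <- nA %/% 2L
    cls <- if (n_dimers == 0) character() else if (exact_proportions) {
      counts <- largest_remainder(config_probs * n_dimers)
      sample(rep(classes, counts))
    } else sample(classes, n_dimers, replace = TRUE, prob = config_probs)
    heads <- list(); hid <- 0L
    add_head <- function(xyz, tubule, dimer_id) {
      hid <<- hid + 1L
      data.frame(head_id = hid, x = xyz[1], y = xyz[2], z = xyz[3],
                 tubule = tubule, dimer_id = dimer_id)
    }
    for (k in seq_len(n_dimers)) {
      s <- runif(1, 20, axis_length_nm - 20)
      base <- c(s, 4, 12)
      off <- switch(cls[k],
                    "1" = c(8, -3.5, 0),
                    "2" = c(0, -3.5, 0),
                    "3" = c(-8, -3.5, 0),
                    "other" = c(6, 0, 0))
      heads[[length(heads) + 1L]] <- add_head(base, "A", k)
      heads[[length(heads) + 1L]] <- add_head(base + off, "A", k)
    }
    if (nA %% 2L == 1L)
      heads[[length(heads) + 1L]] <-
        add_head(c(runif(1, 0, axis_length_nm), 4, 12), "A", NA)
    for (k in seq_len(nB))
      heads[[length(heads) + 1L]] <-
        add_head(c(runif(1, 0, axis_length_nm), -4, -12), "B", NA)
    hdf <- if (length(heads)) do.call(rbind, heads) else
      data.frame(head_id = integer(), x = numeric(), y = numeric(),
                 z = numeric(), tubule = character(), dimer_id = integer())
    ann <- tomo_annotation(paste0("doublet_", d), axis, hdf)
    attr(ann, "true_classes") <- cls
    ann
  })
  attr(anns, "ground_truth") <- list(
    n_doublets = n_doublets, axis_length_nm = axis_length_nm,
    rate_A = rate_A, rate_B = rate_B, config_probs = config_probs,
    seed = seed)
  anns
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  ord <- order(x - fl, decreasing = TRUE)
  fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  as.integer(fl)
}

#' Generate a synthetic peptide-spectrum-match table
#'
#' C-terminal records (70% of the table) are true suffixes of
#' `reference_tail` drawn tyrosinated with probability `frac_Y`
#' (otherwise suffixes of the tail minus its terminal tyrosine); the
#' remainder are internal decoy peptides.  The glutamylation flag is
#' drawn with probability `frac_glu` over all records.  Spectral counts
#' are 1 + Poisson(1).
#'
#' @param frac_Y probability a C-terminal record is tyrosinated.
#' @param frac_glu probability any record carries glutamylation.
#' @param n_records table size.
#' @param reference_tail alpha-tubulin C-terminal sequence ending in Y.
#' @param seed integer.
#' @param ct_fraction fraction of records that are C-terminal.
#' @return data.frame with columns `peptide`, `count`, `mods`, and
#'   attribute `ground_truth`.
#' @export
gen_psm_table <- function(frac_Y = 0.337, frac_glu = 0.0635,
                          n_records = 1e4,
                          reference_tail = "EDLAALEKDFEEVGAESAEGAGEGEGEEY",
                          seed = 1, ct_fraction = 0.7) {
  if (any(c(frac_Y, frac_glu) < 0) || any(c(frac_Y, frac_glu) > 1))
    stop("fractions must be within 0..1")
  set.seed(seed)
  n_ct <- round(n_records * ct_fraction)
  nref <- nchar(reference_tail)
  detyr <- substr(reference_tail, 1, nref - 1)
  is_y <- runif(n_ct) < frac_Y
  suffix_len <- sample(8:20, n_ct, replace = TRUE)
  pep_ct <- ifelse(is_y,
                   substring(reference_tail, nref - suffix_len + 1, nref),
                   substring(detyr, nref - 1 - suffix_len + 1, nref - 1))
  decoys <- c("AVLVDLEPGTMDSVR", "QLFHPEQLITGK", "IHFPLATYAPVISAEK",
              "EIIDLVLDR", "AYHEQLSVAEITNACFEPANQMVK")
  pep_in <- sample(decoys, n_records - n_ct, replace = TRUE)
  peptide <- c(pep_ct, pep_in)
  out <- data.frame(peptide = peptide,
                    count = 1L + rpois(n_records, 1),
                    mods = ifelse(runif(n_records) < frac_glu,
                                  "glutamylation", ""))
  out <- out[sample(n_records), ]
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(frac_Y = frac_Y, frac_glu = frac_glu,
                                    n_records = n_records, seed = seed)
  out
}

#' Generate analytic random-walk trajectories for occupancy tests
#'
#' Isotropic Gaussian random walks of a center-of-geometry starting at
#' `start` (the grid center); a walk is absorbed (flagged, and then
#' frozen at its exit point) once |x - x0| or |y - y0| crosses
#' `absorbing_bound`.  Returned objects are `cg_trajectory`-compatible,
#' with a stationary partner-head series for order-statistic tests.
#'
#' @param n number of walks.
#' @param n_frames frames per walk.
#' @param step_sd nm per frame per axis.
#' @param absorbing_bound nm (use `Inf` for no absorption).
#' @param seed integer.
#' @param start 3-vector, nm.
#' @return list of `cg_trajectory` objects with attribute
#'   `ground_truth`.
#' @export
gen_random_walk_trajectories <- function(n = 100, n_frames = 200,
                                         step_sd = 1, absorbing_bound = Inf,
                                         seed = 1, start = c(0, 0, 0)) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  out <- lapply(seq_len(n), function(k) {
    steps <- matrix(rnorm(3 * n_frames, sd = step_sd), ncol = 3)
    pos <- sweep(apply(steps, 2, cumsum), 2, start, "+")
    if (n_frames == 1) pos <- matrix(pos, 1, 3)
    esc <- which(abs(pos[, 1] - start[1]) > absorbing_bound |
                   abs(pos[, 2] - start[2]) > absorbing_bound)
    if (length(esc) > 0 && esc[1] < n_frames)
      pos[(esc[1] + 1):n_frames, ] <-
        matrix(pos[esc[1], ], n_frames - esc[1], 3, byrow = TRUE)
    structure(list(steps = seq_len(n_frames),
                   com_low = pos,
                   com_high = matrix(start, n_frames, 3, byrow = TRUE),
                   metadata = list(seed = seed, walk = k,
                                   absorbed = length(esc) > 0,
                                   position_id = 2)),
              class = "cg_trajectory")
  })
  attr(out, "ground_truth") <- list(n = n, n_frames = n_frames,
                                    step_sd = step_sd,
                                    absorbing_bound = absorbing_bound,
                                    seed = seed)
  out
}
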