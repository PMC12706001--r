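#' Head density per tubule (heads per 100 nm)
#'
#' density = 100 * (head count assigned to the tubule) / (axis arc length
#' in nm), computed separately for the A- and B-tubule of a doublet
#' annotation.
#'
#' @param ann a tomogram annotation (see [tomo_annotation()]).
#' @return named numeric vector `c(A = , B = )`, heads per 100 nm.
#' @export
head_density <- function(ann) {
  len <- polyline_length(ann$axis)
  if (len <= 0) stop("zero-length axis")
  tab <- table(factor(ann$heads$tubule, levels = c("A", "B")))
  c(A = 100 * unname(tab["A"]) / len, B = 100 * unname(tab["B"]) / len)
}

polyline_length <- function(axis) {
  if (nrow(axis) < 2) stop("axis needs at least 2 points")
  sum(sqrt(rowSums((axis[-1, , drop = FALSE] -
                      axis[-nrow(axis), , drop = FALSE])^2)))
}

#' Tomogram doublet annotation
#'
#' @param doublet_id identifier.
#' @param axis n x 3 matrix (nm), polyline of the doublet axis ordered so
#'   that it runs toward the minus end (`polarity` = +1) or away
#'   (`polarity` = -1).
#' @param heads data.frame with columns `head_id`, `x`, `y`, `z` (nm),
#'   `tubule` ("A"/"B"), `dimer_id` (NA for unpaired heads).
#' @param outward_normal unit 3-vector, outward radial direction used for
#'   configuration chirality.
#' @param polarity +1 or -1.
#' @return object of class `tomo_annotation`.
#' @export
tomo_annotation <- function(doublet_id, axis, heads,
                            outward_normal = c(0, 0, 1), polarity = 1) {
  axis <- as.matrix(axis)
  if (nrow(axis) < 2) stop("axis needs >= 2 points")
  if (nrow(heads) > 0) {
    seg_dist <- function(p) {
      d <- Inf
      for (s in seq_len(nrow(axis) - 1)) {
        a <- axis[s, ]; b <- axis[s + 1, ]
        ab <- b - a
        t0 <- min(1, max(0, sum((p - a) * ab) / sum(ab^2)))
        d <- min(d, sqrt(sum((p - (a + t0 * ab))^2)))
      }
      d
    }
    d <- vapply(seq_len(nrow(heads)), function(k)
      seg_dist(c(heads$x[k], heads$y[k], heads$z[k])), 1)
    if (any(d > 60)) stop("head further than 60 nm from the axis")
    if (!is.null(heads$dimer_id)) {
      tb <- table(heads$dimer_id[!is.na(heads$dimer_id)])
      if (any(tb != 2)) stop("dimer_ids must pair exactly two heads")
    }
  }
  structure(list(doublet_id = doublet_id, axis = axis, heads = heads,
                 outward_normal = outward_normal / sqrt(sum(outward_normal^2)),
                 polarity = polarity),
            class = "tomo_annotation")
}

#' Unpaired two-group comparison
#'
#' Two-sided unpaired Student t test (equal variances by default, the
#' common Prism default; set `welch = TRUE` for the Welch variant).
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param welch use the Welch unequal-variance t test.
#' @return list with `mean_a`, `mean_b`, `sd_a`, `sd_b`, `t`, `df`, `p`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  tt <- t.test(a, b, var.equal = !welch)
  list(mean_a = mean(a), mean_b = mean(b), sd_a = sd(a), sd_b = sd(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Classify a dimer head pair into cryo-ET Configurations 1-3
#'
#' Viewing convention: observer outside the microtubule looking along the
#' minus-end direction (`axis_dir`, the direction of dynein movement)
#' with the outward surface normal pointing up; the right-hand direction
#' is then `axis_dir x outward_normal`.  The head with the larger
#' projection on that direction is the right head.  If the axial offset
#' between the heads is within `axial_tol` the pair is Configuration 2
#' (side by side); otherwise the right head leading (larger minus-end
#' projection) gives Configuration 1 and trailing gives Configuration 3.
#' Laterally coincident pairs (offset below `lateral_tol`) have no
#' defined chirality and return `"other"`.
#'
#' @param head_low,head_partner 3-vectors, nm.
#' @param axis_dir unit 3-vector toward the minus end.
#' @param outward_normal unit 3-vector.
#' @param axial_tol nm (default 4, half a tubulin dimer repeat).
#' @param lateral_tol nm.
#' @return `"1"`, `"2"`, `"3"` or `"other"`.
#' @export
classify_configuration <- function(head_low, head_partner, axis_dir,
                                   outward_normal, axial_tol = 4,
                                   lateral_tol = 1) {
  if (sqrt(sum(axis_dir^2)) == 0 || sqrt(sum(outward_normal^2)) == 0)
    stop("zero-length direction vector")
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  outward_normal <- outward_normal / sqrt(sum(outward_normal^2))
  right <- c(axis_dir[2] * outward_normal[3] - axis_dir[3] * outward_normal[2],
             axis_dir[3] * outward_normal[1] - axis_dir[1] * outward_normal[3],
             axis_dir[1] * outward_normal[2] - axis_dir[2] * outward_normal[1])
  d <- head_partner - head_low
  if (all(d == 0)) stop("heads must be distinct")
  lat <- sum(d * right)
  if (abs(lat) < lateral_tol) return("other")
  # axial positions of the right and left head
  ax_low <- sum(head_low * axis_dir); ax_par <- sum(head_partner * axis_dir)
  right_head_ax <- if (lat > 0) ax_par else ax_low
  left_head_ax <- if (lat > 0) ax_low else ax_par
  off <- right_head_ax - left_head_ax
  if (abs(off) <= axial_tol) "2" else if (off > 0) "1" else "3"
}

#' Configuration class proportions
#'
#' Percentages (100 * count / total) of Configurations 1, 2, 3 and
#' `other`, rounded half-up to one decimal; classes are reported even
#' when zero.
#'
#' @param labels character/numeric vector of labels in
#'   `{"1","2","3","other"}`.
#' @return named numeric vector of percentages.
#' @export
config_proportions <- function(labels) {
  if (length(labels) == 0) stop("no labels")
  labels <- as.character(labels)
  counts <- table(factor(labels, levels = c("1", "2", "3", "other")))
  round_half_up(100 * as.numeric(counts) / length(labels), 1) |>
    setNames(names(counts))
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Classify a peptide against the alpha-tubulin C-terminal tail
#'
#' A peptide that is a suffix of the reference tail ending at the
#' terminal tyrosine is `tyrosinated`; a suffix ending exactly one
#' residue short (at the penultimate glutamate) is `detyrosinated`;
#' anything else (e.g. an internal tryptic peptide) is `internal`.
#'
#' @param peptide one-letter peptide sequence.
#' @param reference_tail the alpha-tubulin C-terminal sequence, which
#'   must end in Y.
#' @return `"tyrosinated"`, `"detyrosinated"` or `"internal"`.
#' @export
classify_ct_peptide <- function(peptide,
                                reference_tail = "EDLAALEKDFEEVGAESAEGAGEGEGEEY") {
  if (nchar(peptide) == 0 || nchar(reference_tail) == 0)
    stop("empty input")
  if (!endsWith(reference_tail, "Y"))
    stop("reference_tail must end in Y")
  if (endsWith(reference_tail, peptide)) return("tyrosinated")
  detyr_ref <- substr(reference_tail, 1, nchar(reference_tail) - 1)
  if (endsWith(detyr_ref, peptide)) return("detyrosinated")
  "internal"
}

#' Tyrosination / detyrosination / glutamylation fractions from PSMs
#'
#' The tyrosinated and detyrosinated fractions are computed over the
#' C-terminal records only; the glutamylated fraction over all records
#' carrying the glutamylation modification flag.  Records are weighted by
#' spectral count by default, or by `intensity` when
#' `weight = "intensity"`.
#'
#' @param records data.frame with columns `peptide`, `count` and
#'   list-column or ;-separated `mods` (see [gen_psm_table()]), and
#'   optionally `intensity`.
#' @param reference_tail the alpha-tubulin C-terminal sequence.
#' @param weight `"count"` or `"intensity"`.
#' @return named numeric vector of percentages
#'   `c(tyrosinated = , detyrosinated = , glutamylated = )`.
#' @export
ptm_fractions <- function(records,
                          reference_tail = "EDLAALEKDFEEVGAESAEGAGEGEGEEY",
                          weight = c("count", "intensity")) {
  weight <- match.arg(weight)
  if (nrow(records) == 0) stop("no records")
  w <- if (weight == "count") records$count else records$intensity
  cls <- vapply(records$peptide, classify_ct_peptide,
                reference_tail = reference_tail, FUN.VALUE = "")
  wy <- sum(w[cls == "tyrosinated"])
  wd <- sum(w[cls == "detyrosinated"])
  if (wy + wd == 0) stop("no C-terminal records")
  glu <- grepl("glutamylation", records$mods)
  c(tyrosinated = 100 * wy / (wy + wd),
    detyrosinated = 100 * wd / (wy + wd),
    glutamylated = 100 * sum(w[glu]) / sum(w))
}

#' Map a modification fraction onto protofilament equivalents
#'
#' round-half-up(fraction/100 * total_pf) with the doublet default of 23
#' protofilaments (13-PF A-tubule + 10-PF B-tubule); e.g. 33.7% of 23
#' gives 8 PFs and 66.3% gives 15 PFs.
#'
#' @param fraction percentage in 0..100.
#' @param total_pf total protofilament count.
#' @return integer protofilament count.
#' @export
pf_equivalents <- function(fraction, total_pf = 23) {
  if (any(fraction < 0 | fraction > 100))
    stop("fraction must be within 0..100")
  if (total_pf < 1) stop("total_pf must be >= 1")
  as.integer(round_half_up(fraction / 100 * total_pf))
}

#' Co-pelleting band fractions and group comparison
#'
#' fraction bound = ppt / (ppt + sup) per replicate; when two constructs
#' are given their replicate fractions are compared with the unpaired t
#' test of [compare_groups()].
#'
#' @param ppt_intensity,sup_intensity non-negative band intensities
#'   (vectors of replicates).
#' @param ppt_b,sup_b optional second construct.
#' @return list with `fraction` (and `fraction_b`, `mean`, `sd`,
#'   `stats` when a second construct is given).
#' @export
binding_fraction <- function(ppt_intensity, sup_intensity,
                             ppt_b = NULL, sup_b = NULL) {
  if (any(ppt_intensity < 0) || any(sup_intensity < 0))
    stop("intensities must be >= 0")
  tot <- ppt_intensity + sup_intensity
  if (any(tot == 0)) stop("ppt and sup must not both be zero")
  fr <- ppt_intensity / tot
  out <- list(fraction = fr, mean = mean(fr), sd = sd(fr))
  if (!is.null(ppt_b)) {
    frb <- binding_fraction(ppt_b, sup_b)$fraction
    out$fraction_b <- frb
    out$stats <- compare_groups(fr, frb)
  }
  out
}

#' Classify all dimer pairs of an annotation
#'
#' Applies [classify_configuration()] to every paired dimer of a
#' [tomo_annotation()], using the local axis direction (overall axis
#' orientation times polarity) and the annotation's outward normal.
#'
#' @param ann a [tomo_annotation()].
#' @param axial_tol,lateral_tol nm, see [classify_configuration()].
#' @return character vector of labels, one per dimer.
#' @export
classify_dimers <- function(ann, axial_tol = 4, lateral_tol = 1) {
  h <- ann$heads
  ids <- unique(h$dimer_id[!is.na(h$dimer_id)])
  axis_vec <- ann$axis[nrow(ann$axis), ] - ann$axis[1, ]
  axis_dir <- ann$polarity * axis_vec / sqrt(sum(axis_vec^2))
  vapply(ids, function(id) {
    pair <- h[!is.na(h$dimer_id) & h$dimer_id == id, ]
    classify_configuration(c(pair$x[1], pair$y[1], pair$z[1]),
                           c(pair$x[2], pair$y[2], pair$z[2]),
                           axis_dir, ann$outward_normal,
                           axial_tol, lateral_tol)
  }, "")
}

#' Read tomogram annotations from JSON
#'
#' Reads the documented annotation container (a JSON array of doublets
#' with `doublet_id`, `polarity`, `outward_normal`, `axis` and `heads`)
#' into a list of [tomo_annotation()] objects.  The packaged 43-dimer
#' synthetic fixture (`system.file("extdata",
#' "synthetic_dimer_configurations.json", package = "dynlattice")`) uses
#' this format.
#'
#' @param path JSON file.
#' @return list of [tomo_annotation()]; any embedded `true_classes`
#'   ground truth is kept as an attribute per annotation.
#' @export
read_tomo_annotations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(x)), function(k) {
    row <- x[k, ]
    ann <- tomo_annotation(row$doublet_id,
                           as.matrix(row$axis[[1]]),
                           as.data.frame(row$heads[[1]]),
                           outward_normal = unlist(row$outward_normal),
                           polarity = row$polarity)
    if (!is.null(row$true_classes))
      attr(ann, "true_classes") <- unlist(row$true_classes)
    ann
  })
}
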