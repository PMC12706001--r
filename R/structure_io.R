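#' Load a PDB or mmCIF structure as a one-bead-per-residue model
#'
#' One bead is placed at each residue's alpha-carbon (positions converted
#' to nm); residues without an alpha-carbon are skipped with a warning.
#' Sequential backbone bonds are added within each chain.  Native contacts
#' follow the standard Go-model construction: alpha-carbon pairs closer
#' than `contact_cutoff` with sequence separation >= `min_seq_sep` within
#' a chain, plus all inter-chain pairs under the cutoff.
#'
#' @param path a PDB (.pdb/.ent) or mmCIF (.cif) file.
#' @param chain_map optional named character vector renaming chains,
#'   e.g. `c(A = "mtbd")`; unmapped chains keep their ids.
#' @param group group label for all beads (default `"mtbd_low"`).
#' @param contact_cutoff nm (default 0.65).
#' @param min_seq_sep minimum |i - j| for intra-chain contacts (default 4).
#' @param assign_charges whether to run [assign_charges()] (default TRUE).
#' @return a [bead_model()].
#' @export
load_structure <- function(path, chain_map = NULL, group = "mtbd_low",
                           contact_cutoff = 0.65, min_seq_sep = 4,
                           assign_charges = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  # one CA per residue (drop altloc duplicates)
  key <- paste(ca$chain, ca$resno, ca$insert)
  ca <- ca[!duplicated(key), , drop = FALSE]
  n_res <- length(unique(paste(at$chain[at$type == "ATOM"],
                               at$resno[at$type == "ATOM"],
                               at$insert[at$type == "ATOM"])))
  if (nrow(ca) == 0) stop("empty selection: no alpha-carbons in ", path)
  if (nrow(ca) < n_res)
    warning(n_res - nrow(ca), " residue(s) without alpha-carbon skipped")
  chain <- as.character(ca$chain)
  if (!is.null(chain_map)) {
    mapped <- chain %in% names(chain_map)
    chain[mapped] <- chain_map[chain[mapped]]
  }
  beads <- data.frame(bead_id = seq_len(nrow(ca)), chain_id = chain,
                      residue_index = ca$resno, residue_name = ca$resid,
                      x = ca$x / 10, y = ca$y / 10, z = ca$z / 10,
                      charge = 0, group = group, anchored = FALSE)
  same <- chain[-1] == chain[-length(chain)]
  bonds <- data.frame(i = which(same), j = which(same) + 1L)
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  nc <- native_contacts_brute(xyz, chain, beads$residue_index,
                              contact_cutoff, min_seq_sep)
  model <- bead_model(beads, bonds, nc)
  if (assign_charges) model <- tryCatch(assign_charges(model),
                                        error = function(e) model)
  model
}

# All-pairs native-contact scan; also used directly by tests as the oracle
# definition of the contact rule.
native_contacts_brute <- function(xyz, chain, resno, cutoff, min_seq_sep) {
  n <- nrow(xyz)
  if (n < 2) return(empty_contacts())
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(empty_contacts())
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- chain[i] != chain[j] | abs(resno[i] - resno[j]) >= min_seq_sep
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0) return(empty_contacts())
  data.frame(i = i, j = j, r0 = d[cbind(i, j)], eps = NA_real_)
}

#' Write a bead model to JSON
#'
#' Documented container: an object with `beads`, `bonds`,
#' `native_contacts` and `tethers` arrays mirroring the [bead_model()]
#' columns.  Round-trips exactly through [read_beads_json()].
#'
#' @param model a [bead_model()].
#' @param path output file.
#' @export
write_beads_json <- function(model, path) {
  jsonlite::write_json(
    list(beads = model$beads, bonds = model$bonds,
         native_contacts = model$native_contacts, tethers = model$tethers),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_beads_json
#' @return `read_beads_json` returns the [bead_model()].
#' @export
read_beads_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(df, template) {
    if (is.null(df) || length(df) == 0 || NROW(df) == 0) return(template)
    as.data.frame(df)
  }
  bead_model(as.data.frame(x$beads), fix(x$bonds, empty_bonds()),
             fix(x$native_contacts, empty_contacts()),
             fix(x$tethers, empty_bonds()))
}

#' Write a bead model as a pseudo-atom PDB for visualization
#'
#' One CA pseudo-atom per bead (nm converted to Angstrom); the bead charge
#' is stored in the B-factor column.
#'
#' @param model a [bead_model()].
#' @param path output file.
#' @export
write_beads_pdb <- function(model, path) {
  b <- model$beads
  chain1 <- substr(b$chain_id, 1, 1)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    b$bead_id %% 100000, b$residue_name, chain1, b$residue_index %% 10000,
    b$x * 10, b$y * 10, b$z * 10, 1, b$charge)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
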