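# Reading, writing and interrogating kinase-domain structures.
#
# A `kinase_structure` is a light S3 container: metadata plus two tibbles,
# one row per residue and one row per atom. Residues are indexed 0-based and
# contiguously (`seq_index`) so that motif arithmetic (DFG+2, HRD-2, ...)
# survives author-numbering gaps and insertion codes; the author number is
# retained for reporting and for matching against experimental structures.

#' Construct a kinase-domain structure object
#'
#' Builds the container used by every downstream module. Most users will not
#' call this directly but obtain structures from [read_structure()] or
#' [make_structure()].
#'
#' @param structure_id Identifier for this structure/model.
#' @param kinase_id Gene/domain identifier shared by all structures of the
#'   same kinase.
#' @param residues Tibble with columns `seq_index` (0-based, contiguous),
#'   `auth_number` (author residue number), `aa` (one-letter code) and
#'   optionally `plddt` (per-residue confidence in \[0, 100\]).
#' @param atoms Tibble with columns `seq_index`, `name` (atom label, e.g.
#'   `"CA"`, `"CZ"`), `element`, and coordinates `x`, `y`, `z` in Angstrom.
#' @param group Kinase group (`"AGC"`, `"CAMK"`, ..., `"unknown"`).
#' @param source One of `"pdb"`, `"af2"`, `"esmfold"`, `"synthetic"`.
#' @param msa_depth Optional MSA depth (predicted sources only).
#' @param chain Chain identifier.
#'
#' @return An object of class `kinase_structure`.
#' @export
kinase_structure <- function(structure_id, kinase_id, residues, atoms,
                             group = "unknown", source = "synthetic",
                             msa_depth = NULL, chain = "A") {
  source <- match.arg(source, structure_sources())
  group <- match.arg(group, kinase_groups())
  residues <- as_tibble(residues)
  atoms <- as_tibble(atoms)
  if (nrow(residues) < 1L) {
    abort("a kinase_structure needs at least one residue",
          class = "kinconform_input_error")
  }
  if (!identical(residues$seq_index, seq_len(nrow(residues)) - 1L)) {
    abort("residue seq_index must be 0-based and contiguous",
          class = "kinconform_input_error")
  }
  if (!"plddt" %in% names(residues)) residues$plddt <- NA_real_
  ok <- is.na(residues$plddt) | (residues$plddt >= 0 & residues$plddt <= 100)
  if (!all(ok)) {
    abort("plddt values must lie in [0, 100]", class = "kinconform_input_error")
  }
  if (anyDuplicated(atoms[, c("seq_index", "name")])) {
    abort("at most one atom per (residue, atom name)",
          class = "kinconform_input_error")
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    abort("atom coordinates must be finite", class = "kinconform_input_error")
  }
  if (!is.null(msa_depth)) {
    assert_count(msa_depth, "msa_depth")
    if (source == "pdb") {
      abort("msa_depth applies to predicted sources only",
            class = "kinconform_input_error")
    }
  }
  structure(
    list(structure_id = as.character(structure_id),
         kinase_id = as.character(kinase_id),
         group = group, source = source,
         msa_depth = if (is.null(msa_depth)) NA_integer_ else as.integer(msa_depth),
         chain = as.character(chain),
         residues = residues, atoms = atoms),
    class = "kinase_structure"
  )
}

#' @export
print.kinase_structure <- function(x, ...) {
  depth <- if (is.na(x$msa_depth)) "" else sprintf(", MSA depth %d", x$msa_depth)
  cat(sprintf("<kinase_structure> %s (%s, %s%s)\n", x$structure_id,
              x$kinase_id, x$source, depth))
  cat(sprintf("  chain %s: %d residues, %d atoms\n", x$chain,
              nrow(x$residues), nrow(x$atoms)))
  mp <- tryCatch(mean_plddt(x), error = function(e) NA_real_)
  if (!is.na(mp)) cat(sprintf("  mean pLDDT %.1f\n", mp))
  invisible(x)
}

#' One-letter sequence of a structure
#'
#' @param s A `kinase_structure`.
#' @return A single character string.
#' @export
structure_sequence <- function(s) {
  paste(s$residues$aa, collapse = "")
}

# Coordinates of atom `name` at residue `seq_index`, or NULL when absent.
atom_xyz <- function(s, seq_index, name) {
  hit <- s$atoms$seq_index == seq_index & s$atoms$name == name
  if (!any(hit)) return(NULL)
  as.numeric(unlist(s$atoms[which(hit)[1L], c("x", "y", "z")]))
}

# n x 3 matrix of Calpha coordinates indexed by seq_index + 1; NA rows where
# the Calpha is missing.
ca_matrix <- function(s) {
  n <- nrow(s$residues)
  m <- matrix(NA_real_, n, 3L)
  ca <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  m[ca$seq_index + 1L, ] <- as.matrix(ca[, c("x", "y", "z")])
  m
}

guess_element <- function(name) {
  # Atom labels here are PDB-style; first alphabetic character is the element
  # for the C/N/O/S side-chain and backbone atoms this package touches.
  substr(gsub("[^A-Za-z].*$", "", name), 1L, 1L)
}

#' Read a kinase-domain structure from a PDB or mmCIF file
#'
#' Parses the file with \pkg{bio3d}, selects one chain, resolves alternate
#' locations to the highest-occupancy copy, drops waters and hetero ligands,
#' and (for predicted sources) maps the B-factor column to per-residue pLDDT.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain Chain identifier; default picks the first chain containing at
#'   least one Calpha.
#' @param source Source tag; `"pdb"` leaves pLDDT unset (the B-factor is a
#'   crystallographic B), predicted sources read pLDDT from it.
#' @param structure_id,kinase_id Identifiers; default to the file name.
#' @param group,msa_depth Optional metadata (see [kinase_structure()]).
#'
#' @return A [kinase_structure()].
#' @export
read_structure <- function(path, chain = NULL,
                           source = c("pdb", "af2", "esmfold", "synthetic"),
                           structure_id = NULL, kinase_id = NULL,
                           group = "unknown", msa_depth = NULL) {
  source <- match.arg(source)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "kinconform_io_error")
  }
  id <- structure_id %||% sub("\\.(pdb|cif|mmcif)$", "", basename(path),
                              ignore.case = TRUE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
    any(grepl("^_atom_site\\.", readLines(path, n = 200L)))
  parsed <- tryCatch(
    if (is_cif) {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      abort(sprintf("could not parse %s: %s", path, conditionMessage(e)),
            class = "kinconform_io_error")
    }
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]          # drop waters/ligands
  if (nrow(at) == 0L) {
    abort("no polymer ATOM records in file", class = "kinconform_io_error")
  }
  at$chain[is.na(at$chain)] <- " "
  if (is.null(chain)) {
    with_ca <- unique(at$chain[at$elety == "CA"])
    if (length(with_ca) == 0L) {
      abort("no chain contains a Calpha atom", class = "kinconform_io_error")
    }
    chain <- with_ca[1L]
  } else if (!chain %in% at$chain) {
    abort(sprintf("chain '%s' absent from %s", chain, path),
          class = "kinconform_io_error")
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (!any(at$elety == "CA")) {
    abort(sprintf("chain '%s' has no Calpha atoms", chain),
          class = "kinconform_io_error")
  }
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1                                # missing occupancy
  at$alt[is.na(at$alt)] <- ""
  # Altloc: per (residue, atom name) keep highest occupancy, ties to the
  # lexicographically first altloc label ('A' before 'B'); file order is
  # restored afterwards so residue numbering follows appearance order.
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]
  rkey <- paste(at$resno, at$insert)
  ridx <- match(rkey, unique(rkey)) - 1L
  first <- !duplicated(rkey)
  aa1 <- suppressWarnings(bio3d::aa321(at$resid[first]))
  aa1[is.na(aa1)] <- "X"
  plddt <- if (source == "pdb") rep(NA_real_, sum(first)) else at$b[first]
  residues <- tibble(
    seq_index = seq_len(sum(first)) - 1L,
    auth_number = as.integer(at$resno[first]),
    insert = as.character(at$insert[first]),
    aa = aa1,
    plddt = as.numeric(plddt)
  )
  atoms <- tibble(
    seq_index = ridx,
    name = as.character(at$elety),
    element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     guess_element(at$elety), at$elesy),
    x = at$x, y = at$y, z = at$z
  )
  kinase_structure(structure_id = id, kinase_id = kinase_id %||% id,
                   residues = residues, atoms = atoms, group = group,
                   source = source, msa_depth = msa_depth, chain = chain)
}

#' Write a structure as a PDB-format file
#'
#' pLDDT (when present) is written into the B-factor column, matching the
#' convention of structure predictors; occupancies are 1.00.
#'
#' @param s A [kinase_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  res <- s$residues[match(at$seq_index, s$residues$seq_index), ]
  aa3 <- suppressWarnings(bio3d::aa123(res$aa))
  aa3[is.na(aa3)] <- "UNK"
  b <- res$plddt
  b[is.na(b)] <- 0
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = res$auth_number, resid = aa3,
                   elety = at$name, chain = rep(s$chain, nrow(at)),
                   o = rep(1, nrow(at)), b = b, eleno = seq_len(nrow(at)))
  invisible(path)
}

#' Mean per-residue pLDDT of a model
#'
#' The model-level confidence score: the arithmetic mean of per-residue pLDDT
#' over all residues.
#'
#' @param s A [kinase_structure()] whose residues all carry pLDDT.
#' @return A score in \[0, 100\].
#' @export
mean_plddt <- function(s) {
  p <- s$residues$plddt
  if (anyNA(p)) {
    abort("structure has residues without pLDDT",
          class = "kinconform_input_error")
  }
  mean(p)
}

#' Keep confidently predicted models
#'
#' Retains models whose mean pLDDT is strictly greater than `threshold`
#' (confident models at the conventional `> 70` cut; `> 90` for the
#' high-accuracy tier). Order is preserved.
#'
#' @param models List of [kinase_structure()] objects.
#' @param threshold Mean-pLDDT cut (strict inequality).
#' @return The retained sublist (possibly empty).
#' @export
filter_confident <- function(models, threshold = 70) {
  stopifnot(is.list(models))
  keep <- vapply(models, function(m) mean_plddt(m) > threshold, logical(1L))
  models[keep]
}
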