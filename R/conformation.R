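# Geometric metrics and the six-state DFG/alphaC classification.
#
# The DFG in/out call uses two anchor distances: d1, from the Calpha four
# residues after the alphaC Glu to the tip of the DFG Phe ring (in DFG-in the
# Phe packs under the alphaC helix, so d1 is short), and d2, from the beta3
# Lys amine to the Phe tip (in DFG-out the Phe flips into the ATP pocket next
# to the Lys, so d2 is short). Both short is the intermediate placement; both
# long is unclassifiable. The alphaC in/out call tests the catalytic Glu-Lys
# salt bridge. The activation-loop state thresholds the Calpha distance
# between the HRD-2 and DFG+2 residues: short (~7 A) means extended, long
# means folded.

#' Signed pseudo-dihedral of four points
#'
#' Torsion angle over four consecutive Calpha positions, IUPAC sign
#' convention: cis = 0 degrees, trans = 180, right-handed rotations positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in (-180, 180\].
#' @export
#' @examples
#' pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # trans
pseudo_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (min(vnorm(b1), vnorm(b2), vnorm(b3)) < 1e-10) {
    abort("degenerate dihedral: zero-length virtual bond",
          class = "kinconform_geometry_error")
  }
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-10 * vnorm(b1) * vnorm(b2) ||
      vnorm(n2) < 1e-10 * vnorm(b2) * vnorm(b3)) {
    abort("degenerate dihedral: collinear point triple",
          class = "kinconform_geometry_error")
  }
  x <- sum(n1 * n2)
  y <- sum(b1 * n2) * vnorm(b2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Tip atom of a side chain: preferred atom if present, else the side-chain
# atom farthest from the Calpha, else the Calpha itself (flagged).
tip_atom <- function(s, seq_index, preferred) {
  p <- atom_xyz(s, seq_index, preferred)
  if (!is.null(p)) return(list(xyz = p, fallback = FALSE))
  rows <- s$atoms[s$atoms$seq_index == seq_index &
                    !s$atoms$name %in% c("CA", "N", "C", "O"), , drop = FALSE]
  ca <- atom_xyz(s, seq_index, "CA")
  if (nrow(rows) > 0L && !is.null(ca)) {
    d <- sqrt((rows$x - ca[1])^2 + (rows$y - ca[2])^2 + (rows$z - ca[3])^2)
    i <- which.max(d)
    return(list(xyz = c(rows$x[i], rows$y[i], rows$z[i]), fallback = FALSE))
  }
  if (is.null(ca)) return(list(xyz = NULL, fallback = TRUE))
  list(xyz = ca, fallback = TRUE)
}

#' Compute the geometric metrics of one structure
#'
#' @param s A [kinase_structure()].
#' @param a Its [motif_anchors()].
#' @param cfg A [conformation_config()].
#' @return A one-row tibble with `dihedral_x` (Calpha torsion over DFG-Asp,
#'   DFG-Phe, DFG-Gly, DFG+1), `dihedral_y` (over DFG-2, DFG-1, DFG-Asp,
#'   DFG-Phe), distances `d1`, `d2`, `salt_bridge`, `loop_dist` (Angstrom),
#'   and `flags`. Metrics whose atoms are missing (or whose geometry is
#'   degenerate) are `NA`.
#' @export
compute_geometry <- function(s, a, cfg = conformation_config()) {
  ca <- ca_matrix(s)
  n <- nrow(ca)
  get_ca <- function(i) {
    if (i < 0L || i > n - 1L) return(NULL)
    v <- ca[i + 1L, ]
    if (anyNA(v)) NULL else v
  }
  flags <- character(0)

  dihed <- function(idx) {
    pts <- lapply(idx, get_ca)
    if (any(vapply(pts, is.null, logical(1L)))) return(NA_real_)
    tryCatch(pseudo_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
             error = function(e) NA_real_)
  }
  dihedral_x <- dihed(a$idx_dfg_asp + 0:3)
  dihedral_y <- dihed(c(a$idx_dfg_asp - 2L, a$idx_dfg_asp - 1L,
                        a$idx_dfg_asp, a$idx_dfg_phe))

  phe <- tip_atom(s, a$idx_dfg_phe, "CZ")
  lys <- tip_atom(s, a$idx_beta3_lys, "NZ")
  if (phe$fallback || lys$fallback) flags <- c(flags, "tip_fallback")

  ca_glu4 <- get_ca(a$idx_alphaC_glu + 4L)
  d1 <- if (is.null(ca_glu4) || is.null(phe$xyz)) NA_real_ else dist3(ca_glu4, phe$xyz)
  d2 <- if (is.null(lys$xyz) || is.null(phe$xyz)) NA_real_ else dist3(lys$xyz, phe$xyz)

  oe1 <- atom_xyz(s, a$idx_alphaC_glu, "OE1")
  oe2 <- atom_xyz(s, a$idx_alphaC_glu, "OE2")
  nz <- atom_xyz(s, a$idx_beta3_lys, "NZ")
  sb_fallback <- FALSE
  if (!is.null(nz) && (!is.null(oe1) || !is.null(oe2))) {
    cand <- c(if (!is.null(oe1)) dist3(oe1, nz),
              if (!is.null(oe2)) dist3(oe2, nz))
    salt_bridge <- min(cand)
  } else {
    glu_ca <- get_ca(a$idx_alphaC_glu)
    lys_ca <- get_ca(a$idx_beta3_lys)
    if (!is.null(glu_ca) && !is.null(lys_ca)) {
      salt_bridge <- dist3(glu_ca, lys_ca)
      sb_fallback <- TRUE
      flags <- c(flags, "salt_bridge_ca_fallback")
    } else {
      salt_bridge <- NA_real_
    }
  }

  hrd2 <- get_ca(a$idx_hrd - 2L)
  dfgp2 <- get_ca(a$idx_dfg_asp + 4L)
  loop_dist <- if (is.null(hrd2) || is.null(dfgp2)) NA_real_ else dist3(hrd2, dfgp2)

  tibble(dihedral_x = dihedral_x, dihedral_y = dihedral_y,
         d1 = d1, d2 = d2, salt_bridge = salt_bridge,
         sb_fallback = sb_fallback, loop_dist = loop_dist,
         flags = join_flags(flags))
}

#' DFG in/out/intermediate state from anchor distances
#'
#' With default thresholds `tau_d1 = tau_d2 = 11` Angstrom: `in` when the Phe
#' tip sits under the alphaC helix (`d1 <= tau_d1`) and away from the beta3
#' Lys (`d2 > tau_d2`); `out` for the reverse; `inter` when both distances
#' are short; `unassigned` when both are long or a metric is unavailable.
#'
#' @param d1,d2 Numeric vectors of distances (Angstrom); `NA` allowed.
#' @param cfg A [conformation_config()].
#' @return Character vector over `c("in", "out", "inter", "unassigned")`.
#' @export
classify_dfg <- function(d1, d2, cfg = conformation_config()) {
  dplyr::case_when(
    is.na(d1) | is.na(d2) ~ "unassigned",
    d1 <= cfg$tau_d1 & d2 > cfg$tau_d2 ~ "in",
    d1 > cfg$tau_d1 & d2 <= cfg$tau_d2 ~ "out",
    d1 <= cfg$tau_d1 & d2 <= cfg$tau_d2 ~ "inter",
    TRUE ~ "unassigned"
  )
}

#' alphaC-helix in/out state from the Glu-Lys salt bridge
#'
#' `in` when the conserved-Glu carboxyl to beta3-Lys amine distance is within
#' `tau_salt_bridge` (default 4.5 Angstrom); when only Calpha atoms are
#' available the Calpha-Calpha criterion `tau_salt_bridge_ca` (default 12) is
#' applied instead (callers should carry the low-confidence flag).
#'
#' @param salt_bridge Numeric vector (Angstrom); `NA` allowed.
#' @param sb_fallback Logical vector: was the Calpha-Calpha fallback used?
#' @param cfg A [conformation_config()].
#' @return Character vector over `c("in", "out", "undetermined")`.
#' @export
classify_alphaC <- function(salt_bridge, sb_fallback = FALSE,
                            cfg = conformation_config()) {
  tau <- ifelse(sb_fallback, cfg$tau_salt_bridge_ca, cfg$tau_salt_bridge)
  dplyr::case_when(
    is.na(salt_bridge) ~ "undetermined",
    salt_bridge <= tau ~ "in",
    TRUE ~ "out"
  )
}

#' Activation-loop state from the HRD-2 to DFG+2 distance
#'
#' Short distances (around 7 Angstrom) indicate an extended loop, long
#' distances a folded one; the boundary (default 10 Angstrom) belongs to
#' `extended`.
#'
#' @param loop_dist Numeric vector (Angstrom); `NA` gives `"unavailable"`.
#' @param cfg A [conformation_config()].
#' @return Character vector over `c("extended", "folded", "unavailable")`.
#' @export
activation_loop_state <- function(loop_dist, cfg = conformation_config()) {
  dplyr::case_when(
    is.na(loop_dist) ~ "unavailable",
    loop_dist <= cfg$tau_loop ~ "extended",
    TRUE ~ "folded"
  )
}

# (dfg, alphaC) -> six-way label. DFGinter outranks the alphaC state; an
# undetermined alphaC demotes an otherwise-classified DFG state to Unassigned.
combine_states <- function(dfg_state, alphaC_state) {
  dplyr::case_when(
    dfg_state == "inter" ~ "DFGinter",
    dfg_state == "unassigned" ~ "Unassigned",
    alphaC_state == "undetermined" ~ "Unassigned",
    dfg_state == "in" & alphaC_state == "in" ~ "CIDI",
    dfg_state == "in" & alphaC_state == "out" ~ "CODI",
    dfg_state == "out" & alphaC_state == "in" ~ "CIDO",
    dfg_state == "out" & alphaC_state == "out" ~ "CODO"
  )
}

#' Classify one structure into the six-state vocabulary
#'
#' Computes the geometric metrics and maps them to the combined
#' DFG/alphaC-helix label: (in, in) = CIDI, (in, out) = CODI, (out, in) =
#' CIDO, (out, out) = CODO, intermediate DFG = DFGinter (the alphaC state is
#' not split for the intermediate placement), anything unclassifiable =
#' Unassigned. The activation-loop state and mean pLDDT (when available) are
#' attached.
#'
#' @param s A [kinase_structure()].
#' @param a Its [motif_anchors()]; default detects them.
#' @param cfg A [conformation_config()].
#' @return A one-row tibble (`structure_id`, `kinase_id`, `group`, `source`,
#'   `msa_depth`, `dfg_seq`, the metric columns, `dfg_state`, `alphaC_state`,
#'   `label`, `loop_state`, `mean_plddt`, `flags`, `excluded`).
#' @export
call_conformation <- function(s, a = NULL, cfg = conformation_config()) {
  if (is.null(a)) a <- detect_motifs(s, cfg)
  m <- compute_geometry(s, a, cfg)
  dfg_state <- classify_dfg(m$d1, m$d2, cfg)
  alphaC_state <- classify_alphaC(m$salt_bridge, m$sb_fallback, cfg)
  label <- combine_states(dfg_state, alphaC_state)
  flags <- m$flags
  if (dfg_state %in% c("in", "out") && alphaC_state == "undetermined") {
    flags <- join_flags(c(flags, "alphaC_undetermined"))
  }
  mp <- tryCatch(mean_plddt(s), error = function(e) NA_real_)
  tibble(
    structure_id = s$structure_id, kinase_id = s$kinase_id,
    group = s$group, source = s$source, msa_depth = s$msa_depth,
    dfg_seq = a$dfg_seq,
    dihedral_x = m$dihedral_x, dihedral_y = m$dihedral_y,
    d1 = m$d1, d2 = m$d2, salt_bridge = m$salt_bridge,
    loop_dist = m$loop_dist,
    dfg_state = dfg_state, alphaC_state = alphaC_state, label = label,
    loop_state = activation_loop_state(m$loop_dist, cfg),
    mean_plddt = mp, flags = flags, excluded = FALSE,
    exclude_reason = NA_character_
  )
}

#' Classify a set of structures
#'
#' Maps [call_conformation()] over a list of structures, resolving anchors
#' from an annotation table when one is supplied (annotation overrides
#' detection) and falling back to sequence detection otherwise. Structures
#' whose anchoring fails are not classified; they appear as rows with
#' `excluded = TRUE` and are counted separately by downstream distribution
#' functions — exclusion bookkeeping mirrors discarding kinases whose motif
#' residues cannot be identified.
#'
#' @param structures List of [kinase_structure()] objects.
#' @param annotations Optional annotation tibble with columns `kinase_id`,
#'   `auth_dfg_asp`, `auth_hrd`, `auth_alphaC_glu`, `auth_beta3_lys`
#'   (`NA` = detect).
#' @param cfg A [conformation_config()].
#' @return A tibble with one row per structure (see [call_conformation()]).
#' @export
classify_structures <- function(structures, annotations = NULL,
                                cfg = conformation_config()) {
  purrr::map_dfr(structures, function(s) {
    a <- tryCatch(resolve_anchors(s, annotations, cfg),
                  kinconform_anchor_error = function(e) e)
    if (inherits(a, "error")) {
      mp <- tryCatch(mean_plddt(s), error = function(e) NA_real_)
      return(tibble(
        structure_id = s$structure_id, kinase_id = s$kinase_id,
        group = s$group, source = s$source, msa_depth = s$msa_depth,
        dfg_seq = NA_character_, dihedral_x = NA_real_, dihedral_y = NA_real_,
        d1 = NA_real_, d2 = NA_real_, salt_bridge = NA_real_,
        loop_dist = NA_real_, dfg_state = NA_character_,
        alphaC_state = NA_character_, label = NA_character_,
        loop_state = NA_character_, mean_plddt = mp, flags = "",
        excluded = TRUE, exclude_reason = conditionMessage(a)
      ))
    }
    call_conformation(s, a, cfg)
  })
}
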