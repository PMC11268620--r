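# Locating the catalytic-motif residues every geometric metric depends on:
# the DFG triplet opening the activation loop, the HRD His upstream of it,
# the conserved alphaC Glu and its beta3 Lys salt-bridge partner.

#' Motif anchor set
#'
#' Positions (0-based `seq_index`) of the catalytic motif residues of one
#' structure, plus the observed 3-mer at the DFG position.
#'
#' @param idx_dfg_asp,idx_hrd,idx_alphaC_glu,idx_beta3_lys Anchor indices.
#' @param dfg_seq Observed 3-mer at the DFG position (e.g. `"DFG"`, `"DYG"`).
#' @param provenance `"annotation"` or `"detected"`.
#' @param n_residues Chain length, for bounds checking.
#' @return An object of class `motif_anchors` with fields `idx_dfg_asp`,
#'   `idx_dfg_phe`, `idx_dfg_gly`, `idx_hrd`, `idx_alphaC_glu`,
#'   `idx_beta3_lys`, `dfg_seq`, `provenance`.
#' @export
motif_anchors <- function(idx_dfg_asp, idx_hrd, idx_alphaC_glu, idx_beta3_lys,
                          dfg_seq, provenance = c("annotation", "detected"),
                          n_residues) {
  provenance <- match.arg(provenance)
  idx <- c(idx_dfg_asp, idx_hrd, idx_alphaC_glu, idx_beta3_lys)
  if (any(idx < 0L) || idx_dfg_asp + 2L > n_residues - 1L) {
    abort("anchor indices fall outside the structure",
          class = "kinconform_anchor_error")
  }
  if (!(idx_hrd < idx_dfg_asp) ||
      !(idx_beta3_lys < idx_alphaC_glu && idx_alphaC_glu < idx_dfg_asp)) {
    abort("anchor ordering violated (need Lys < Glu < DFG and HRD < DFG)",
          class = "kinconform_anchor_error")
  }
  structure(
    list(idx_dfg_asp = as.integer(idx_dfg_asp),
         idx_dfg_phe = as.integer(idx_dfg_asp) + 1L,
         idx_dfg_gly = as.integer(idx_dfg_asp) + 2L,
         idx_hrd = as.integer(idx_hrd),
         idx_alphaC_glu = as.integer(idx_alphaC_glu),
         idx_beta3_lys = as.integer(idx_beta3_lys),
         dfg_seq = as.character(dfg_seq), provenance = provenance),
    class = "motif_anchors"
  )
}

#' @export
print.motif_anchors <- function(x, ...) {
  cat(sprintf("<motif_anchors> %s (%s)\n", x$dfg_seq, x$provenance))
  cat(sprintf("  beta3-Lys %d < alphaC-Glu %d < HRD %d < DFG %d-%d\n",
              x$idx_beta3_lys, x$idx_alphaC_glu, x$idx_hrd,
              x$idx_dfg_asp, x$idx_dfg_gly))
  invisible(x)
}

#' Anchor motifs from a per-kinase annotation record
#'
#' Maps author residue numbers supplied by an annotation table onto the
#' 0-based chain index. Annotation, when available, always overrides
#' detection. A missing annotated residue is an anchoring failure: the
#' structure is excluded downstream and counted.
#'
#' @param s A [kinase_structure()].
#' @param annotation A one-row data frame or named list with
#'   `auth_dfg_asp`, `auth_hrd`, `auth_alphaC_glu`, `auth_beta3_lys`.
#' @return A [motif_anchors()] with provenance `"annotation"`.
#' @export
anchor_from_annotation <- function(s, annotation) {
  need <- c("auth_dfg_asp", "auth_hrd", "auth_alphaC_glu", "auth_beta3_lys")
  if (!all(need %in% names(annotation))) {
    abort(sprintf("annotation must provide: %s", paste(need, collapse = ", ")),
          class = "kinconform_input_error")
  }
  to_idx <- function(auth) {
    i <- which(s$residues$auth_number == as.integer(auth))
    if (length(i) == 0L) {
      abort(sprintf("annotated residue %s absent from chain of %s",
                    auth, s$structure_id),
            class = "kinconform_anchor_error")
    }
    s$residues$seq_index[i[1L]]
  }
  idx_asp <- to_idx(annotation$auth_dfg_asp)
  if (idx_asp + 2L > nrow(s$residues) - 1L) {
    abort("DFG triplet truncated at chain end", class = "kinconform_anchor_error")
  }
  motif_anchors(
    idx_dfg_asp = idx_asp,
    idx_hrd = to_idx(annotation$auth_hrd),
    idx_alphaC_glu = to_idx(annotation$auth_alphaC_glu),
    idx_beta3_lys = to_idx(annotation$auth_beta3_lys),
    dfg_seq = substr(structure_sequence(s), idx_asp + 1L, idx_asp + 3L),
    provenance = "annotation", n_residues = nrow(s$residues)
  )
}

#' Detect catalytic motifs from sequence
#'
#' Substitution-tolerant scan of the one-letter sequence: an HRD-like 3-mer
#' (`[HY]R[DN]`) followed 10-40 residues later by a DFG-like 3-mer
#' (`D[FYWL]G`), taking the pairing whose gap is closest to 20 residues;
#' beta3-Lys is the last Lys in a window upstream of HRD and the alphaC Glu
#' the first Glu in a window downstream of that Lys. Windows and patterns
#' come from [conformation_config()].
#'
#' @param s A [kinase_structure()] with at least 60 residues.
#' @param cfg A [conformation_config()].
#' @return A [motif_anchors()] with provenance `"detected"`.
#' @export
detect_motifs <- function(s, cfg = conformation_config()) {
  seq1 <- structure_sequence(s)
  n <- nchar(seq1)
  if (n < 60L) {
    abort("chain too short for motif detection (< 60 residues)",
          class = "kinconform_anchor_error")
  }
  find_all <- function(pattern) {
    m <- gregexpr(sprintf("(?=(%s))", pattern), seq1, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L   # 0-based starts
  }
  hrd_hits <- find_all(cfg$hrd_pattern)
  dfg_hits <- find_all(cfg$dfg_pattern)
  if (length(hrd_hits) == 0L || length(dfg_hits) == 0L) {
    abort("no HRD-like or DFG-like motif found", class = "kinconform_anchor_error")
  }
  pairs <- expand.grid(hrd = hrd_hits, dfg = dfg_hits)
  pairs$gap <- pairs$dfg - pairs$hrd
  pairs <- pairs[pairs$gap >= cfg$gap_range[1] & pairs$gap <= cfg$gap_range[2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) {
    abort("no admissible HRD/DFG pairing", class = "kinconform_anchor_error")
  }
  pairs <- pairs[order(abs(pairs$gap - cfg$gap_target), pairs$hrd, pairs$dfg), ,
                 drop = FALSE]
  idx_hrd <- pairs$hrd[1L]
  idx_dfg <- pairs$dfg[1L]
  chars <- strsplit(seq1, "")[[1L]]
  lys_lo <- max(0L, idx_hrd + cfg$lys_window[1]) + 1L      # 1-based bounds
  lys_hi <- max(0L, idx_hrd + cfg$lys_window[2]) + 1L
  ks <- which(chars == "K")
  ks <- ks[ks >= lys_lo & ks <= lys_hi]
  if (length(ks) == 0L) {
    abort("no beta3 Lys candidate in window", class = "kinconform_anchor_error")
  }
  idx_lys <- max(ks) - 1L
  glu_lo <- idx_lys + cfg$glu_window[1] + 1L
  glu_hi <- min(n, idx_lys + cfg$glu_window[2] + 1L)
  es <- which(chars == "E")
  es <- es[es >= glu_lo & es <= glu_hi]
  if (length(es) == 0L) {
    abort("no alphaC Glu candidate in window", class = "kinconform_anchor_error")
  }
  idx_glu <- min(es) - 1L
  motif_anchors(idx_dfg_asp = idx_dfg, idx_hrd = idx_hrd,
                idx_alphaC_glu = idx_glu, idx_beta3_lys = idx_lys,
                dfg_seq = substr(seq1, idx_dfg + 1L, idx_dfg + 3L),
                provenance = "detected", n_residues = n)
}

#' Observed DFG-position 3-mer
#'
#' Used as the equality gate for TM-score comparisons: scores are only
#' computed between structures sharing the same DFG-position sequence.
#'
#' @param a A [motif_anchors()].
#' @return The 3-mer string.
#' @export
dfg_motif_sequence <- function(a) {
  stopifnot(inherits(a, "motif_anchors"))
  a$dfg_seq
}

# Resolve anchors for one structure: annotation row if available, else
# detection. Returns a motif_anchors or signals kinconform_anchor_error.
resolve_anchors <- function(s, annotations = NULL, cfg = conformation_config()) {
  if (!is.null(annotations)) {
    row <- annotations[annotations$kinase_id == s$kinase_id, , drop = FALSE]
    if (nrow(row) >= 1L &&
        !is.na(row$auth_dfg_asp[1L])) {
      return(anchor_from_annotation(s, as.list(row[1L, ])))
    }
  }
  detect_motifs(s, cfg)
}
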