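# Structural superposition and TM-score with the model-as-reference and
# DFG-motif-gating conventions.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation superposing `coordsB` onto
#' `coordsA`; reflections are excluded by the usual determinant sign
#' correction.
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates (n >= 3,
#'   not all collinear).
#' @return List with `rotation` (3 x 3, det = +1), `translation` (length-3),
#'   and `rmsd`; the transform maps B as `B %*% rotation + translation`.
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB) || ncol(coordsA) != 3L || ncol(coordsB) != 3L) {
    abort("need two equal-length n x 3 coordinate matrices",
          class = "kinconform_input_error")
  }
  n <- nrow(coordsA)
  if (n < 3L) {
    abort("need at least 3 point pairs", class = "kinconform_input_error")
  }
  cA <- colMeans(coordsA); cB <- colMeans(coordsB)
  A <- sweep(coordsA, 2L, cA); B <- sweep(coordsB, 2L, cB)
  if (max(svd(A)$d[2], svd(B)$d[2]) < 1e-8) {
    abort("all points collinear; rotation underdetermined",
          class = "kinconform_geometry_error")
  }
  H <- crossprod(B, A)                       # 3x3: t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # B %*% R ~ A (centred)
  fit <- B %*% R
  rmsd <- sqrt(sum((fit - A)^2) / n)
  list(rotation = R, translation = as.numeric(cA - cB %*% R), rmsd = rmsd)
}

tm_d0 <- function(l_ref) {
  if (l_ref > 21) max(1.24 * (l_ref - 15)^(1 / 3) - 1.8, 0.5) else 0.5
}

# TM-score of paired coordinates under a given rigid transform.
tm_of_transform <- function(A, B, R, tvec, d0, l_ref) {
  fit <- sweep(B %*% R, 2L, tvec, "+")
  d2 <- rowSums((fit - A)^2)
  sum(1 / (1 + d2 / d0^2)) / l_ref
}

#' TM-score of a structure pair, model as reference
#'
#' Computes the template-modelling score normalising by the length of the
#' first argument (the model), so flexible regions unresolved in the
#' experimental structure lower the score rather than escaping it. Residue
#' correspondence is by author numbering (same kinase, same construct);
#' unmatched residues are dropped from the pairing but the reference length
#' keeps every model residue. The reported score is the maximum over a
#' superposition search: a global Kabsch fit plus Kabsch fits seeded on
#' contiguous fragments (full, half and quarter length), each refined by
#' iteratively re-superposing on residue pairs within a distance cutoff
#' schedule `d0, 2 d0, 4 d0` until the retained pair set is stable.
#'
#' @param model Reference [kinase_structure()] (sets `l_ref` and `d0`).
#' @param other Structure compared against it.
#' @return Object of class `tm_result`: `tm`, `d0`, `l_ref`, `n_common`,
#'   `rotation`, `translation`, `rmsd_all`, `flags`.
#' @export
tm_score <- function(model, other) {
  res_m <- model$residues; res_o <- other$residues
  common <- intersect(res_m$auth_number, res_o$auth_number)
  caM <- ca_matrix(model); caO <- ca_matrix(other)
  im <- res_m$seq_index[match(common, res_m$auth_number)] + 1L
  io <- res_o$seq_index[match(common, res_o$auth_number)] + 1L
  ok <- !is.na(rowSums(caM[im, , drop = FALSE])) &
    !is.na(rowSums(caO[io, , drop = FALSE]))
  im <- im[ok]; io <- io[ok]
  n_common <- length(im)
  if (n_common < 3L) {
    abort("fewer than 3 common residues with Calpha",
          class = "kinconform_input_error")
  }
  A <- caM[im, , drop = FALSE]
  B <- caO[io, , drop = FALSE]
  l_ref <- nrow(res_m)
  d0 <- tm_d0(l_ref)
  flags <- if (l_ref <= 21) "d0_floor" else ""

  best <- list(tm = -Inf)
  consider <- function(R, tvec) {
    tm <- tm_of_transform(A, B, R, tvec, d0, l_ref)
    if (tm > best$tm) best <<- list(tm = tm, R = R, tvec = tvec)
  }
  refine <- function(R, tvec) {
    for (d_cut in c(d0, 2 * d0, 4 * d0)) {
      kept_prev <- integer(0)
      for (it in seq_len(20L)) {
        fit <- sweep(B %*% R, 2L, tvec, "+")
        d <- sqrt(rowSums((fit - A)^2))
        kept <- which(d < d_cut)
        if (length(kept) < 3L || identical(kept, kept_prev)) break
        kept_prev <- kept
        k <- tryCatch(kabsch_superpose(A[kept, , drop = FALSE],
                                       B[kept, , drop = FALSE]),
                      error = function(e) NULL)
        if (is.null(k)) break
        R <- k$rotation; tvec <- k$translation
      }
    }
    consider(R, tvec)
  }

  g <- kabsch_superpose(A, B)
  consider(g$rotation, g$translation)         # the one-shot global fit
  refine(g$rotation, g$translation)
  for (frac in c(1, 2, 4)) {
    flen <- max(3L, floor(n_common / frac))
    starts <- seq(1L, max(1L, n_common - flen + 1L), by = max(1L, floor(flen / 2)))
    for (st in starts) {
      idx <- st:(st + flen - 1L)
      k <- tryCatch(kabsch_superpose(A[idx, , drop = FALSE],
                                     B[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(k)) next
      consider(k$rotation, k$translation)
      refine(k$rotation, k$translation)
    }
  }
  fit <- sweep(B %*% best$R, 2L, best$tvec, "+")
  rmsd_all <- sqrt(mean(rowSums((fit - A)^2)))
  structure(
    list(tm = best$tm, d0 = d0, l_ref = l_ref, n_common = n_common,
         rotation = best$R, translation = best$tvec, rmsd_all = rmsd_all,
         model_id = model$structure_id, other_id = other$structure_id,
         flags = flags),
    class = "tm_result"
  )
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> %s vs %s: TM = %.4f (d0 = %.2f, l_ref = %d, %d pairs)\n",
              x$model_id, x$other_id, x$tm, x$d0, x$l_ref, x$n_common))
  invisible(x)
}

#' Best TM-score per model against gated reference structures
#'
#' For every model, scores it (as reference) against every structure of the
#' same kinase that shares its DFG-position 3-mer (the DFG-motif gate,
#' focusing comparisons on catalytically compatible subunits), and keeps the
#' highest score; ties break toward the earliest target `structure_id`.
#' Models with no gated partner are reported as uncompared (`best_tm = NA`).
#'
#' @param models List of [kinase_structure()] models.
#' @param structures List of [kinase_structure()] comparison structures.
#' @param gate_dfg Apply the DFG-motif equality gate (default `TRUE`).
#' @param annotations Optional anchor annotation table (see
#'   [classify_structures()]); detection is used otherwise.
#' @param cfg A [conformation_config()].
#' @return Tibble with one row per model: `model_id`, `kinase_id`,
#'   `msa_depth`, `dfg_seq`, `best_target`, `best_tm`, `n_compared`.
#' @export
best_tm_summary <- function(models, structures, gate_dfg = TRUE,
                            annotations = NULL, cfg = conformation_config()) {
  motif_of <- function(s) {
    tryCatch(dfg_motif_sequence(resolve_anchors(s, annotations, cfg)),
             kinconform_anchor_error = function(e) NA_character_)
  }
  target_motifs <- vapply(structures, motif_of, character(1L))
  target_ids <- vapply(structures, function(s) s$structure_id, character(1L))
  target_kin <- vapply(structures, function(s) s$kinase_id, character(1L))
  purrr::map_dfr(models, function(m) {
    motif <- motif_of(m)
    sel <- target_kin == m$kinase_id & !is.na(target_motifs)
    if (gate_dfg) sel <- sel & !is.na(motif) & target_motifs == motif
    sel <- which(sel)
    base <- tibble(model_id = m$structure_id, kinase_id = m$kinase_id,
                   msa_depth = m$msa_depth, dfg_seq = motif)
    if (length(sel) == 0L) {
      return(dplyr::mutate(base, best_target = NA_character_,
                           best_tm = NA_real_, n_compared = 0L))
    }
    ord <- sel[order(target_ids[sel])]       # stable tie-break by target id
    tms <- vapply(ord, function(j) tm_score(m, structures[[j]])$tm, numeric(1L))
    i <- which.max(tms)                      # first max -> earliest id
    dplyr::mutate(base, best_target = target_ids[ord[i]], best_tm = tms[i],
                  n_compared = length(ord))
  })
}
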