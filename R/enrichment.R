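# Ligand-enrichment curves and AUCs from docking score tables.
#
# The curve plots the percent of known actives retrieved against the top
# percent of the score-ranked compound database examined, keeping only each
# compound's best pose; the area under it, scaled to 0-100, summarises how
# much better than random (AUC 50) a model ranks actives above decoys.

#' Enrichment curve and AUC for one model's score table
#'
#' Reduces each compound to its best-scoring pose, ranks all compounds
#' (direction-aware; docking energies are lower-better), and accumulates the
#' retrieval curve. Tied scores share the midpoint position, which the
#' trapezoidal area realises by linear interpolation across the tied block.
#'
#' @param records Tibble with columns `compound_id`, `label` (`"active"` /
#'   `"decoy"`), `score`, and optionally `model_id` (one model only) and
#'   `pose_rank`.
#' @param direction `"lower_better"` (default, docking energies) or
#'   `"higher_better"`.
#' @return Object of class `enrichment_result`: `model_id`, `curve` (tibble
#'   `pct_db_examined`, `pct_actives_found`, from (0, 0) to (100, 100)),
#'   `auc` on the 0-100 scale, `n_actives`, `n_decoys`.
#' @export
enrichment_curve <- function(records, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  records <- as_tibble(records)
  if (!all(c("compound_id", "label", "score") %in% names(records))) {
    abort("records need compound_id, label, score columns",
          class = "kinconform_input_error")
  }
  if (!all(records$label %in% c("active", "decoy"))) {
    abort("label must be 'active' or 'decoy'", class = "kinconform_input_error")
  }
  if (!all(is.finite(records$score))) {
    abort("scores must be finite", class = "kinconform_input_error")
  }
  model_id <- if ("model_id" %in% names(records)) {
    ids <- unique(records$model_id)
    if (length(ids) > 1L) {
      abort("records span several models; see enrichment_aucs()",
            class = "kinconform_input_error")
    }
    ids
  } else NA_character_
  # Best pose per compound.
  best <- records |>
    dplyr::group_by(.data$compound_id, .data$label) |>
    dplyr::summarise(score = if (direction == "lower_better") min(.data$score)
                     else max(.data$score), .groups = "drop")
  n_act <- sum(best$label == "active")
  n_dec <- sum(best$label == "decoy")
  if (n_act < 1L || n_dec < 1L) {
    abort("need at least one active and one decoy after top-pose reduction",
          class = "kinconform_input_error")
  }
  r <- if (direction == "lower_better") best$score else -best$score
  ord <- order(r)
  r <- r[ord]
  act <- best$label[ord] == "active"
  n <- length(r)
  # Collapse tied-score blocks: curve vertices at block ends only, so the
  # trapezoid interpolates linearly across ties (midpoint tie handling).
  block_end <- which(!duplicated(r, fromLast = TRUE))
  cum_act <- cumsum(act)[block_end]
  x <- c(0, 100 * block_end / n)
  y <- c(0, 100 * cum_act / n_act)
  auc <- sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2) / 100
  structure(
    list(model_id = model_id,
         curve = tibble(pct_db_examined = x, pct_actives_found = y),
         auc = auc, n_actives = n_act, n_decoys = n_dec,
         direction = direction),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: AUC = %.2f (%d actives, %d decoys)\n",
              x$model_id %||% "?", x$auc, x$n_actives, x$n_decoys))
  invisible(x)
}

#' Enrichment AUCs for a multi-model score table
#'
#' @param records Score tibble with `model_id`, `compound_id`, `label`,
#'   `score` (and optionally `pose_rank`).
#' @param direction Passed to [enrichment_curve()].
#' @return Tibble `model_id`, `auc`, `n_actives`, `n_decoys`.
#' @export
enrichment_aucs <- function(records, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  records |>
    dplyr::group_by(.data$model_id) |>
    dplyr::group_modify(function(d, key) {
      e <- enrichment_curve(d, direction)
      tibble(auc = e$auc, n_actives = e$n_actives, n_decoys = e$n_decoys)
    }) |>
    dplyr::ungroup()
}

#' Assign mean-pLDDT confidence bins
#'
#' The three half-open confidence tiers used for stratified enrichment
#' summaries: `100 > x >= 90`, `90 > x >= 80`, `80 > x >= 70` (boundaries
#' belong to the higher bin; 100 itself falls in the top bin). Values below
#' 70 give `NA`.
#'
#' @param mean_plddt Numeric vector.
#' @return Factor with the three bin labels.
#' @export
plddt_bin <- function(mean_plddt) {
  labs <- c("80 > x >= 70", "90 > x >= 80", "100 > x >= 90")
  idx <- dplyr::case_when(
    is.na(mean_plddt) ~ NA_integer_,
    mean_plddt >= 90 ~ 3L,
    mean_plddt >= 80 ~ 2L,
    mean_plddt >= 70 ~ 1L,
    TRUE ~ NA_integer_
  )
  factor(labs[idx], levels = labs)
}

#' Stratified enrichment summaries
#'
#' Joins per-model AUCs to conformation calls and summarises per group:
#' mean, sample standard deviation (n - 1 denominator; a single model gets
#' sd 0 with a flag), maximum, and model count.
#'
#' @param aucs Tibble from [enrichment_aucs()] (needs `model_id`, `auc`).
#' @param calls Call tibble (needs `structure_id` matching `model_id`, plus
#'   `kinase_id`, `label`, `mean_plddt`).
#' @param grouping Any of `"kinase"`, `"plddt_bin"`, `"label"`.
#' @return Tibble with the grouping columns plus `n`, `avg_auc`, `sd_auc`,
#'   `max_auc`, `flags`.
#' @export
summarize_enrichment <- function(aucs, calls,
                                 grouping = c("kinase", "plddt_bin", "label")) {
  grouping <- match.arg(grouping, several.ok = TRUE)
  unmatched <- setdiff(aucs$model_id, calls$structure_id)
  if (length(unmatched)) {
    abort(sprintf("model_id(s) with no conformation call: %s",
                  paste(unmatched, collapse = ", ")),
          class = "kinconform_input_error")
  }
  joined <- dplyr::inner_join(
    aucs, calls, by = c(model_id = "structure_id")
  ) |>
    dplyr::mutate(plddt_bin = plddt_bin(.data$mean_plddt),
                  kinase = .data$kinase_id)
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n = dplyr::n(),
      avg_auc = mean(.data$auc),
      sd_auc = if (dplyr::n() > 1L) sd(.data$auc) else 0,
      max_auc = max(.data$auc),
      flags = if (dplyr::n() > 1L) "" else "single_model_sd",
      .groups = "drop"
    )
}

#' One-sample test of enrichment against random selection
#'
#' One-sided one-sample t-test of the mean AUC against the random-retrieval
#' value 50 (alternative: greater). A constant input equal to 50 returns the
#' zero-t convention p = 0.5; other constant inputs are flagged degenerate.
#'
#' @param aucs Numeric vector of AUCs on the 0-100 scale, n >= 2.
#' @return A `kin_test` object.
#' @export
test_vs_random <- function(aucs) {
  if (length(aucs) < 2L) {
    abort("need at least two AUCs", class = "kinconform_input_error")
  }
  if (sd(aucs) == 0) {
    if (mean(aucs) == 50) {
      return(new_kin_test("one_sample_t", statistic = 0, p_value = 0.5,
                          alternative = "greater"))
    }
    return(new_kin_test("one_sample_t",
                        statistic = sign(mean(aucs) - 50) * Inf,
                        p_value = if (mean(aucs) > 50) 0 else 1,
                        alternative = "greater", flags = "degenerate"))
  }
  tt <- stats::t.test(aucs, mu = 50, alternative = "greater")
  new_kin_test("one_sample_t", statistic = unname(tt$statistic),
               p_value = tt$p.value, alternative = "greater")
}
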