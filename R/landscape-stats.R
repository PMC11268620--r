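# Distributions of conformation calls across strata and the statistical
# machinery used to compare them.

new_kin_test <- function(test, statistic, p_value, alternative,
                         n_boot = NA_integer_, correction = NA_character_,
                         flags = "") {
  structure(
    list(test = test, statistic = as.numeric(statistic),
         p_value = as.numeric(p_value), alternative = alternative,
         n_boot = as.integer(n_boot), correction = correction,
         flags = flags),
    class = "kin_test"
  )
}

#' @export
print.kin_test <- function(x, ...) {
  cat(sprintf("<kin_test> %s (%s)\n  statistic = %.4g, p = %.4g\n",
              x$test, x$alternative, x$statistic, x$p_value))
  if (!is.na(x$n_boot)) cat(sprintf("  n_boot = %d\n", x$n_boot))
  if (nzchar(x$flags)) cat(sprintf("  flags: %s\n", x$flags))
  invisible(x)
}

# Coerce a distribution tibble (single stratum), a named count vector, or a
# call tibble into counts over the six labels.
as_label_counts <- function(x) {
  labs <- conformation_labels()
  if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), labs)
    if (length(bad)) {
      abort(sprintf("unknown conformation labels: %s", paste(bad, collapse = ", ")),
            class = "kinconform_input_error")
    }
    out <- setNames(numeric(length(labs)), labs)
    out[names(x)] <- x
    return(out)
  }
  if (is.data.frame(x)) {
    if (all(c("label", "count") %in% names(x))) {
      extra <- setdiff(names(x), c("label", "count", "fraction", "n", "n_excluded"))
      if (length(extra) > 0L && nrow(dplyr::distinct(x[extra])) > 1L) {
        abort("distribution covers several strata; pass one stratum",
              class = "kinconform_input_error")
      }
      return(as_label_counts(setNames(x$count, x$label)))
    }
    if ("label" %in% names(x)) {
      tab <- table(factor(x$label[!is.na(x$label)], levels = labs))
      return(setNames(as.numeric(tab), labs))
    }
  }
  abort("cannot interpret input as conformation counts",
        class = "kinconform_input_error")
}

#' Conformation distribution per stratum
#'
#' Counts and fractions of the six conformational labels, optionally
#' stratified (e.g. by `source`, `group` or `msa_depth`). Structures excluded
#' by anchoring failures are counted separately per stratum and never enter
#' the fractions.
#'
#' @param calls Call tibble from [classify_structures()] (or any tibble with
#'   `label` and optionally `excluded`).
#' @param stratify_by Character vector of column names to stratify by.
#' @return A tibble with the stratification columns plus `label`, `count`,
#'   `fraction`, `n` (classified) and `n_excluded`.
#' @export
conformation_distribution <- function(calls, stratify_by = character()) {
  bad <- setdiff(stratify_by, names(calls))
  if (length(bad)) {
    abort(sprintf("unknown stratification field(s): %s", paste(bad, collapse = ", ")),
          class = "kinconform_input_error")
  }
  if (!"excluded" %in% names(calls)) calls$excluded <- FALSE
  labs <- conformation_labels()
  calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratify_by))) |>
    dplyr::group_modify(function(d, key) {
      cls <- d[!d$excluded, , drop = FALSE]
      tab <- table(factor(cls$label, levels = labs))
      n <- sum(tab)
      tibble(label = labs, count = as.integer(tab),
             fraction = if (n > 0) as.numeric(tab) / n else NA_real_,
             n = n, n_excluded = sum(d$excluded))
    }) |>
    dplyr::ungroup()
}

#' Multi-model fractional contributions by repeated sampling
#'
#' When one kinase has several calls (several deposited models), its
#' contribution to each conformation fraction is estimated by drawing
#' `n_samples` random samples of one call per kinase, accumulating the
#' fractional contributions, repeating `n_repeats` times and averaging.
#' Kinases with a single call contribute deterministically.
#'
#' @param calls Call tibble with `kinase_id` and `label` (excluded rows are
#'   dropped).
#' @param n_samples Samples of one-conformation-per-kinase per repeat.
#' @param n_repeats Number of repeats averaged.
#' @param seed Optional RNG seed for bit-identical output.
#' @return A tibble `label`, `fraction` over the six labels.
#' @export
multi_model_fraction <- function(calls, n_samples = 1000, n_repeats = 10,
                                 seed = NULL) {
  assert_count(n_samples, "n_samples")
  assert_count(n_repeats, "n_repeats")
  if ("excluded" %in% names(calls)) calls <- calls[!calls$excluded, , drop = FALSE]
  labs <- conformation_labels()
  by_kinase <- split(match(calls$label, labs), calls$kinase_id)
  n_kin <- length(by_kinase)
  if (n_kin == 0L) {
    abort("no classified calls", class = "kinconform_input_error")
  }
  with_seed_maybe(seed, {
    acc <- matrix(0, n_repeats, length(labs))
    for (r in seq_len(n_repeats)) {
      counts <- numeric(length(labs))
      for (lab_idx in by_kinase) {
        if (length(lab_idx) == 1L) {
          counts[lab_idx] <- counts[lab_idx] + n_samples
        } else {
          draw <- sample(lab_idx, n_samples, replace = TRUE)
          counts <- counts + tabulate(draw, nbins = length(labs))
        }
      }
      acc[r, ] <- counts / (n_samples * n_kin)
    }
    tibble(label = labs, fraction = colMeans(acc))
  })
}

#' Bootstrap comparison of one conformation's fraction
#'
#' Draws `n_boot` multinomial resamples (each side at its own dataset size)
#' from the two distributions' fractions, records the focal label's count in
#' each resample, and compares the two count vectors with a one-sided
#' Wilcoxon rank-sum test (midranks, normal approximation with continuity
#' correction).
#'
#' @param distA,distB Distributions: tibbles from
#'   [conformation_distribution()] (one stratum each) or named count vectors.
#' @param label The focal conformation label.
#' @param n_boot Number of bootstrap resamples per side.
#' @param alternative `"greater"` (A's fraction exceeds B's), `"less"`, or
#'   `"two.sided"`.
#' @param seed Optional RNG seed.
#' @return A `kin_test` object (see [tidy.kin_test()]).
#' @export
bootstrap_fraction_compare <- function(distA, distB, label, n_boot = 1000,
                                       alternative = c("greater", "less", "two.sided"),
                                       seed = NULL) {
  alternative <- match.arg(alternative)
  assert_count(n_boot, "n_boot")
  if (!label %in% conformation_labels()) {
    abort(sprintf("unknown label '%s'", label), class = "kinconform_input_error")
  }
  cA <- as_label_counts(distA)
  cB <- as_label_counts(distB)
  nA <- sum(cA); nB <- sum(cB)
  if (nA == 0 || nB == 0) {
    abort("both distributions need a positive total",
          class = "kinconform_input_error")
  }
  with_seed_maybe(seed, {
    xA <- rmultinom(n_boot, size = nA, prob = cA / nA)[label, ]
    xB <- rmultinom(n_boot, size = nB, prob = cB / nB)[label, ]
    wt <- stats::wilcox.test(xA, xB, alternative = alternative,
                             exact = FALSE, correct = n_boot >= 50)
    new_kin_test("bootstrap_wilcoxon", statistic = unname(wt$statistic),
                 p_value = wt$p.value, alternative = alternative,
                 n_boot = n_boot)
  })
}

#' Contingency-table comparison of two distributions
#'
#' Builds the 2 x k table of conformation counts (labels with zero column
#' totals dropped) and applies Fisher's exact test (exact for 2 x 2;
#' fixed-seed Monte-Carlo with `B` tables otherwise) or the plain Pearson
#' Chi-squared test with (r-1)(c-1) degrees of freedom.
#'
#' @param distA,distB Distributions (as in [bootstrap_fraction_compare()]).
#' @param method `"fisher"` or `"chisq"`.
#' @param B Monte-Carlo table count for Fisher beyond 2 x 2.
#' @param seed Seed for the Monte-Carlo Fisher p-value.
#' @return A `kin_test` object.
#' @export
contingency_compare <- function(distA, distB, method = c("fisher", "chisq"),
                                B = 100000, seed = 1) {
  method <- match.arg(method)
  tab <- rbind(as_label_counts(distA), as_label_counts(distB))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (sum(tab) == 0) {
    abort("all-zero contingency table", class = "kinconform_input_error")
  }
  if (method == "fisher") {
    ft <- if (ncol(tab) <= 2L) {
      stats::fisher.test(tab)
    } else {
      with_seed_maybe(seed, stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
    }
    new_kin_test("fisher_exact",
                 statistic = if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_,
                 p_value = ft$p.value, alternative = "two.sided")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    new_kin_test("chi_squared", statistic = unname(ct$statistic),
                 p_value = ct$p.value, alternative = "two.sided")
  }
}

#' Bonferroni-corrected per-comparison significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_comparisons Number of comparisons (e.g. `choose(7, 2) = 21`
#'   unordered pairs of seven MSA-depth distributions).
#' @return `alpha / n_comparisons`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, choose(7, 2)) # 0.00238
bonferroni_threshold <- function(alpha, n_comparisons) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)", class = "kinconform_input_error")
  }
  assert_count(n_comparisons, "n_comparisons")
  alpha / n_comparisons
}

#' Count predicted conformations unobserved experimentally
#'
#' For each MSA depth and confidence threshold, a confident model (mean pLDDT
#' strictly above the threshold) is novel when its conformation label is not
#' in the reference (experimentally observed) label set of its kinase;
#' kinases absent from the reference contribute all their confident models.
#'
#' @param model_calls Call tibble with `kinase_id`, `msa_depth`, `label`,
#'   `mean_plddt` (excluded rows dropped automatically).
#' @param reference_calls Tibble `kinase_id`, `label`: the observed label
#'   sets (one row per observed kinase-label pair); kinases with no rows have
#'   empty reference sets.
#' @param thresholds Mean-pLDDT cuts, default the confident (`> 70`) and
#'   high-accuracy (`> 90`) tiers.
#' @return A tibble with one row per (threshold, msa_depth): `kinase_count`
#'   (distinct kinases with at least one novel model), `total_models`, and
#'   one column per conformation label. The attribute `pooled_kinases` holds
#'   the distinct novel-kinase count across all depths per threshold.
#' @export
novelty_table <- function(model_calls, reference_calls, thresholds = c(70, 90)) {
  if ("excluded" %in% names(model_calls)) {
    model_calls <- model_calls[!model_calls$excluded, , drop = FALSE]
  }
  labs <- conformation_labels()
  ref_sets <- lapply(split(reference_calls$label, reference_calls$kinase_id), unique)
  pooled <- integer(0)
  out <- purrr::map_dfr(thresholds, function(thr) {
    conf <- model_calls[model_calls$mean_plddt > thr, , drop = FALSE]
    ref <- ref_sets[conf$kinase_id]
    seen <- purrr::map2_lgl(conf$label, ref, function(lab, rs) {
      !is.null(rs) && lab %in% rs
    })
    novel <- conf[!seen, , drop = FALSE]
    pooled[[as.character(thr)]] <<- dplyr::n_distinct(novel$kinase_id)
    novel |>
      dplyr::group_by(msa_depth) |>
      dplyr::group_modify(function(d, key) {
        tab <- table(factor(d$label, levels = labs))
        dplyr::bind_cols(
          tibble(kinase_count = dplyr::n_distinct(d$kinase_id),
                 total_models = nrow(d)),
          as_tibble(as.list(setNames(as.integer(tab), labs)))
        )
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(threshold = thr, .before = 1L)
  })
  # Depths with zero novel models should still appear as all-zero rows.
  depths <- sort(unique(model_calls$msa_depth))
  full <- tidyr::expand_grid(threshold = thresholds, msa_depth = depths)
  out <- dplyr::left_join(full, out, by = c("threshold", "msa_depth")) |>
    dplyr::mutate(dplyr::across(-c("threshold", "msa_depth"),
                                ~ tidyr::replace_na(.x, 0L)))
  attr(out, "pooled_kinases") <- setNames(as.integer(pooled), names(pooled))
  out
}

#' Unique named conformations per kinase
#'
#' Counts distinct labels among the five named conformations (CIDI, CIDO,
#' CODI, CODO, DFGinter) per kinase; Unassigned is a sink, not a
#' conformation, and is not counted.
#'
#' @param calls Call tibble with `kinase_id` and `label`.
#' @return Tibble `kinase_id`, `n_conformations`.
#' @export
unique_conformation_counts <- function(calls) {
  if ("excluded" %in% names(calls)) calls <- calls[!calls$excluded, , drop = FALSE]
  calls |>
    dplyr::filter(.data$label %in% named_conformations()) |>
    dplyr::group_by(.data$kinase_id) |>
    dplyr::summarise(n_conformations = dplyr::n_distinct(.data$label),
                     .groups = "drop")
}

#' Paired comparison of per-kinase conformation counts
#'
#' One-sided paired t-test that the mean of `countsA` exceeds that of
#' `countsB` over a shared kinase set (e.g. unique conformations per kinase
#' predicted at one MSA depth versus observed experimentally). Zero-variance
#' differences are handled by convention: p = 1 when the common difference is
#' zero, p = 0 (flagged `degenerate`) otherwise.
#'
#' @param countsA,countsB Equal-length paired numeric vectors, n >= 2.
#' @return A `kin_test` object.
#' @export
compare_conformation_counts_paired <- function(countsA, countsB) {
  if (length(countsA) != length(countsB)) {
    abort("paired vectors must have equal length", class = "kinconform_input_error")
  }
  if (length(countsA) < 2L) {
    abort("need at least two pairs", class = "kinconform_input_error")
  }
  d <- countsA - countsB
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(new_kin_test("paired_t", statistic = 0, p_value = 1,
                          alternative = "greater", flags = "degenerate"))
    }
    return(new_kin_test("paired_t", statistic = sign(mean(d)) * Inf,
                        p_value = if (mean(d) > 0) 0 else 1,
                        alternative = "greater", flags = "degenerate"))
  }
  tt <- stats::t.test(countsA, countsB, paired = TRUE, alternative = "greater")
  new_kin_test("paired_t", statistic = unname(tt$statistic),
               p_value = tt$p.value, alternative = "greater")
}
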