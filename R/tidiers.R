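# broom-style tidiers for the package's result objects.

#' Tidy a statistical comparison result
#'
#' @param x A `kin_test` object.
#' @param ... Unused.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `alternative`,
#'   `n_boot`, `correction`, `flags`.
#' @export
tidy.kin_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         alternative = x$alternative, n_boot = x$n_boot,
         correction = x$correction, flags = x$flags)
}

#' @rdname tidy.kin_test
#' @export
glance.kin_test <- function(x, ...) tidy(x)

#' Tidy a TM-score result
#'
#' @param x A `tm_result` object from [tm_score()].
#' @param ... Unused.
#' @return One-row tibble: `model_id`, `other_id`, `tm`, `d0`, `l_ref`,
#'   `n_common`, `rmsd_all`, `flags`.
#' @export
tidy.tm_result <- function(x, ...) {
  tibble(model_id = x$model_id, other_id = x$other_id, tm = x$tm, d0 = x$d0,
         l_ref = x$l_ref, n_common = x$n_common, rmsd_all = x$rmsd_all,
         flags = x$flags)
}

#' @rdname tidy.tm_result
#' @export
glance.tm_result <- function(x, ...) tidy(x)

#' Tidy an enrichment result
#'
#' `tidy()` returns the curve points; `glance()` the one-row summary.
#'
#' @param x An `enrichment_result` from [enrichment_curve()].
#' @param ... Unused.
#' @return A tibble (see Description).
#' @export
tidy.enrichment_result <- function(x, ...) {
  dplyr::mutate(x$curve, model_id = x$model_id, .before = 1L)
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(model_id = x$model_id, auc = x$auc, n_actives = x$n_actives,
         n_decoys = x$n_decoys)
}
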