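# Enrichment curves, AUCs, stratified summaries, and the random baseline.

perfect_table <- function(n_act = 50, n_dec = 2500) {
  tibble::tibble(
    compound_id = c(sprintf("a%04d", 1:n_act), sprintf("d%04d", 1:n_dec)),
    label = rep(c("active", "decoy"), c(n_act, n_dec)),
    score = c(seq(-10, -9, length.out = n_act), seq(-5, -1, length.out = n_dec))
  )
}

test_that("a perfect ranking gives the analytic step-curve AUC", {
  # 50 actives strictly above 2,500 decoys: triangle up to 50/2550 of the
  # database then flat at 100%, area = 99.0196 on the 0-100 scale.
  e <- enrichment_curve(perfect_table())
  expect_equal(e$auc, 100 * (1 - 0.5 * 50 / 2550), tolerance = 1e-10)
  expect_equal(round(e$auc, 2), 99.02)
  expect_equal(e$n_actives, 50L)
  expect_equal(e$n_decoys, 2500L)
  # Curve contract: starts at (0,0), ends at (100,100), monotone.
  expect_equal(e$curve$pct_db_examined[1], 0)
  expect_equal(e$curve$pct_actives_found[1], 0)
  expect_equal(utils::tail(e$curve$pct_db_examined, 1), 100)
  expect_equal(utils::tail(e$curve$pct_actives_found, 1), 100)
  expect_true(all(diff(e$curve$pct_db_examined) >= 0))
  expect_true(all(diff(e$curve$pct_actives_found) >= 0))
})

test_that("reversing the ranking mirrors the AUC around 50", {
  tab <- perfect_table()
  fwd <- enrichment_curve(tab)$auc
  rev_tab <- tab
  rev_tab$score <- -rev_tab$score
  expect_equal(enrichment_curve(rev_tab)$auc, 100 - fwd, tolerance = 1e-10)
  # Equivalently: same scores, opposite direction.
  expect_equal(enrichment_curve(tab, direction = "higher_better")$auc,
               100 - fwd, tolerance = 1e-10)
})

test_that("only the top pose of each compound contributes", {
  tab <- tibble::tibble(
    compound_id = c("lig1", "lig1", "dec1", "dec2"),
    label = c("active", "active", "decoy", "decoy"),
    score = c(-9.1, -7.0, -8.0, -6.0)
  )
  e <- enrichment_curve(tab)
  # With pose -9.1 the active ranks first of three compounds.
  dedup <- tibble::tibble(compound_id = c("lig1", "dec1", "dec2"),
                          label = c("active", "decoy", "decoy"),
                          score = c(-9.1, -8.0, -6.0))
  expect_equal(e$auc, enrichment_curve(dedup)$auc)
  expect_equal(e$n_actives, 1L)
  # Had the -7.0 pose been used the active would rank second.
  worse <- dedup
  worse$score[1] <- -7.0
  expect_gt(e$auc, enrichment_curve(worse)$auc)
})

test_that("AUC is a rank statistic: invariant under monotone score transforms", {
  withr::with_seed(71, {
    tab <- make_score_table(n_actives = 30, n_decoys = 300, mu_active = -8,
                            mu_decoy = -6.5, seed = 72)$records
    base <- enrichment_curve(tab)$auc
    tr1 <- dplyr::mutate(tab, score = exp(score / 2))
    tr2 <- dplyr::mutate(tab, score = 3 * score + 100)
    expect_equal(enrichment_curve(tr1)$auc, base, tolerance = 1e-12)
    expect_equal(enrichment_curve(tr2)$auc, base, tolerance = 1e-12)
  })
})

test_that("fully tied scores give the chance AUC through midpoint ties", {
  tab <- tibble::tibble(compound_id = c("a1", "d1", "d2", "d3"),
                        label = c("active", "decoy", "decoy", "decoy"),
                        score = rep(-5, 4))
  expect_equal(enrichment_curve(tab)$auc, 50)
})

test_that("degenerate score tables are rejected", {
  no_dec <- tibble::tibble(compound_id = "a", label = "active", score = -5)
  expect_error(enrichment_curve(no_dec), class = "kinconform_input_error")
  bad_lab <- tibble::tibble(compound_id = "a", label = "unknown", score = -5)
  expect_error(enrichment_curve(bad_lab), class = "kinconform_input_error")
})

test_that("estimated AUC tracks the normal-CDF closed form", {
  st <- make_score_table(mu_active = -8, mu_decoy = -6, sigma = 1, seed = 77)
  expect_equal(st$expected_auc, 100 * pnorm(sqrt(2)))
  expect_equal(enrichment_curve(st$records)$auc, st$expected_auc,
               tolerance = 0.04)  # relative tolerance ~3.7 AUC units
})

test_that("stratified summaries use sample sd, max, and the pLDDT bins", {
  aucs <- tibble::tibble(model_id = c("m1", "m2", "m3"),
                         auc = c(60, 80, 45),
                         n_actives = 50L, n_decoys = 2500L)
  calls <- tibble::tibble(structure_id = c("m1", "m2", "m3"),
                          kinase_id = c("KIN1", "KIN1", "KIN2"),
                          label = c("CIDI", "CIDI", "CODO"),
                          mean_plddt = c(90, 83.2, 71))
  sm <- summarize_enrichment(aucs, calls, grouping = "kinase")
  k1 <- sm[sm$kinase == "KIN1", ]
  expect_equal(k1$avg_auc, 70)
  expect_equal(k1$sd_auc, sd(c(60, 80)))
  expect_equal(round(k1$sd_auc, 3), 14.142)
  expect_equal(k1$max_auc, 80)
  k2 <- sm[sm$kinase == "KIN2", ]
  expect_equal(k2$sd_auc, 0)
  expect_match(k2$flags, "single_model_sd")
  # Boundary 90 belongs to the upper bin; bins are the three half-open tiers.
  expect_equal(as.character(plddt_bin(c(90, 83.2, 71, 100))),
               c("100 > x >= 90", "90 > x >= 80", "80 > x >= 70",
                 "100 > x >= 90"))
  expect_true(is.na(plddt_bin(65)))
  sb <- summarize_enrichment(aucs, calls, grouping = "plddt_bin")
  expect_equal(sb$n[sb$plddt_bin == "100 > x >= 90"], 1L)
  expect_error(
    summarize_enrichment(dplyr::mutate(aucs, model_id = paste0(model_id, "X")),
                         calls),
    class = "kinconform_input_error"
  )
})

test_that("the one-sample test against random follows its conventions", {
  expect_equal(test_vs_random(rep(50, 10))$p_value, 0.5)
  withr::with_seed(83, {
    strong <- rnorm(100, 65, 10)
    expect_lt(test_vs_random(strong)$p_value, 1e-10)
    # Size calibration: null AUCs drawn at 50 reject at roughly alpha.
    rate <- mean(vapply(1:200, function(i) {
      test_vs_random(rnorm(100, 50, 10))$p_value < 0.05
    }, logical(1)))
    expect_gte(rate, 0.01)
    expect_lte(rate, 0.12)
  })
  expect_error(test_vs_random(50), class = "kinconform_input_error")
})

test_that("per-model AUC tables and tidiers agree with the curve objects", {
  st1 <- make_score_table(mu_active = -8, mu_decoy = -6, n_actives = 20,
                          n_decoys = 200, model_id = "mA", seed = 85)
  st2 <- make_score_table(mu_active = -6, mu_decoy = -6, n_actives = 20,
                          n_decoys = 200, model_id = "mB", seed = 86)
  recs <- dplyr::bind_rows(st1$records, st2$records)
  tab <- enrichment_aucs(recs)
  expect_equal(nrow(tab), 2L)
  eA <- enrichment_curve(st1$records)
  expect_equal(tab$auc[tab$model_id == "mA"], eA$auc)
  g <- glance(eA)
  expect_equal(g$auc, eA$auc)
  td <- tidy(eA)
  expect_true(all(c("pct_db_examined", "pct_actives_found") %in% names(td)))
})
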