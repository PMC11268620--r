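# Distributions, bootstrap/contingency/t-test comparisons, novelty counting.

fake_calls <- function(labels, kinase = paste0("k", seq_along(labels)),
                       excluded = FALSE) {
  tibble::tibble(structure_id = paste0("s", seq_along(labels)),
                 kinase_id = kinase, label = labels,
                 excluded = rep(excluded, length.out = length(labels)))
}

test_that("distributions count, fraction and conserve excluded structures", {
  d <- conformation_distribution(fake_calls(rep("CIDI", 4)))
  expect_equal(d$fraction[d$label == "CIDI"], 1)
  expect_equal(sum(d$fraction), 1)
  d2 <- conformation_distribution(fake_calls(c(rep("CIDI", 3), "CODI")))
  expect_equal(d2$fraction[d2$label == "CIDI"], 0.75)
  expect_equal(d2$fraction[d2$label == "CODI"], 0.25)
  # 10 structures, 2 excluded upstream: fractions over the 8 classified.
  calls <- fake_calls(c(rep("CIDI", 6), rep("CODO", 2), NA, NA),
                      excluded = c(rep(FALSE, 8), TRUE, TRUE))
  d3 <- conformation_distribution(calls)
  expect_equal(unique(d3$n), 8L)
  expect_equal(unique(d3$n_excluded), 2L)
  expect_equal(d3$fraction[d3$label == "CIDI"], 6 / 8)
  expect_equal(sum(d3$fraction), 1, tolerance = 1e-12)
  expect_error(conformation_distribution(calls, "no_such_field"),
               class = "kinconform_input_error")
})

test_that("stratified distributions split by the requested fields", {
  calls <- dplyr::bind_rows(
    dplyr::mutate(fake_calls(rep("CIDI", 4)), source = "pdb"),
    dplyr::mutate(fake_calls(rep("CODO", 2)), source = "af2")
  )
  d <- conformation_distribution(calls, stratify_by = "source")
  expect_equal(d$fraction[d$source == "pdb" & d$label == "CIDI"], 1)
  expect_equal(d$fraction[d$source == "af2" & d$label == "CODO"], 1)
})

test_that("multi-model averaging matches its closed-form expectations", {
  # Every kinase single-call: equals the plain distribution, any seed.
  calls <- fake_calls(c("CIDI", "CIDI", "CODI", "CODO"))
  f1 <- multi_model_fraction(calls, seed = 1)
  f2 <- multi_model_fraction(calls, seed = 99)
  plain <- conformation_distribution(calls)
  expect_equal(f1$fraction, plain$fraction[match(f1$label, plain$label)])
  expect_equal(f1, f2)
  # One two-call kinase: expected contribution 0.5/0.5 within +/- 0.02.
  calls2 <- fake_calls(c("CIDI", "CODI"), kinase = c("k1", "k1"))
  f <- multi_model_fraction(calls2, seed = 5)
  expect_equal(f$fraction[f$label == "CIDI"], 0.5, tolerance = 0.04)
  expect_equal(f$fraction[f$label == "CODI"], 0.5, tolerance = 0.04)
  expect_equal(sum(f$fraction), 1, tolerance = 1e-12)
  # Fixed seed: bit-identical repetition.
  expect_identical(multi_model_fraction(calls2, seed = 7),
                   multi_model_fraction(calls2, seed = 7))
  expect_error(multi_model_fraction(calls2, n_samples = 0),
               class = "kinconform_input_error")
})

test_that("bootstrap comparison separates grossly different fractions", {
  distA <- c(CIDI = 450, CODI = 50)
  distB <- c(CIDI = 50, CODI = 450)
  r <- bootstrap_fraction_compare(distA, distB, "CIDI", seed = 3,
                                  alternative = "greater")
  expect_lt(r$p_value, 1e-6)
  expect_identical(r$test, "bootstrap_wilcoxon")
  expect_equal(r$n_boot, 1000L)
  # Reproducible bit-for-bit under a fixed seed.
  r2 <- bootstrap_fraction_compare(distA, distB, "CIDI", seed = 3,
                                   alternative = "greater")
  expect_identical(tidy(r), tidy(r2))
  expect_error(bootstrap_fraction_compare(distA, distB, "CIDI", n_boot = 0),
               class = "kinconform_input_error")
  expect_error(bootstrap_fraction_compare(distA, distB, "NOTALABEL"),
               class = "kinconform_input_error")
})

test_that("contingency comparisons match exact references", {
  # Perfectly homogeneous 2x2: Fisher p = 1.
  expect_equal(contingency_compare(c(CIDI = 5, CODI = 5),
                                   c(CIDI = 5, CODI = 5), "fisher")$p_value, 1)
  # A strongly associated table against the enumeration oracle.
  tab <- matrix(c(8, 1, 2, 9), 2, 2)
  r <- contingency_compare(c(CIDI = 8, CODI = 2), c(CIDI = 1, CODI = 9),
                           "fisher")
  expect_equal(r$p_value, oracle_fisher_2x2(tab), tolerance = 1e-10)
  # 30 random tables with modest margins.
  withr::with_seed(23, {
    for (i in 1:30) {
      t4 <- matrix(rpois(4, 6), 2, 2)
      if (any(colSums(t4) == 0)) next
      got <- contingency_compare(
        c(CIDI = t4[1, 1], CODI = t4[1, 2]),
        c(CIDI = t4[2, 1], CODI = t4[2, 2]), "fisher")$p_value
      expect_equal(got, oracle_fisher_2x2(t4), tolerance = 1e-10)
    }
  })
  # Identical count vectors: chi-squared statistic 0, p 1.
  r2 <- contingency_compare(c(CIDI = 10, CODI = 5, CIDO = 5),
                            c(CIDI = 10, CODI = 5, CIDO = 5), "chisq")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # Monte-Carlo Fisher beyond 2x2 is seed-reproducible.
  dA <- c(CIDI = 20, CODI = 8, CIDO = 4)
  dB <- c(CIDI = 6, CODI = 14, CIDO = 10)
  expect_equal(contingency_compare(dA, dB, "fisher", B = 20000, seed = 9)$p_value,
               contingency_compare(dA, dB, "fisher", B = 20000, seed = 9)$p_value)
  expect_error(contingency_compare(c(CIDI = 0), c(CIDI = 0), "fisher"),
               class = "kinconform_input_error")
})

test_that("Bonferroni threshold reproduces the multi-depth comparison level", {
  expect_equal(signif(bonferroni_threshold(0.05, choose(7, 2)), 3), 0.00238)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), class = "kinconform_input_error")
  expect_error(bonferroni_threshold(1.2, 3), class = "kinconform_input_error")
})

test_that("novelty accounting matches hand-computed set differences", {
  mc <- tibble::tibble(
    kinase_id = c("k1", "k1", "k2", "k2", "k2"),
    msa_depth = c(8L, 8L, 8L, 8L, 16L),
    label = c("CIDI", "CIDO", "CODO", "CIDI", "CODI"),
    mean_plddt = c(95, 80, 92, 75, 91),
    excluded = FALSE
  )
  rc <- tibble::tibble(kinase_id = "k1", label = "CIDI")
  nt <- novelty_table(mc, rc)
  r70_8 <- nt[nt$threshold == 70 & nt$msa_depth == 8, ]
  # k1: CIDI seen, CIDO novel. k2: no reference, both depth-8 models novel.
  expect_equal(r70_8$total_models, 3L)
  expect_equal(r70_8$CIDO, 1L)
  expect_equal(r70_8$CODO, 1L)
  expect_equal(r70_8$CIDI, 1L)
  expect_equal(r70_8$kinase_count, 2L)
  r90_8 <- nt[nt$threshold == 90 & nt$msa_depth == 8, ]
  expect_equal(r90_8$total_models, 1L)          # only the 92-confidence CODO
  expect_equal(r90_8$CODO, 1L)
  # Pooled distinct kinases across depths.
  expect_equal(unname(attr(nt, "pooled_kinases")["70"]), 2L)
  # total_models equals the per-label row sum everywhere.
  labcols <- conformation_labels()
  expect_true(all(nt$total_models == rowSums(nt[, labcols])))
  # 90-threshold cells never exceed 70-threshold cells.
  n70 <- nt[nt$threshold == 70, labcols]
  n90 <- nt[nt$threshold == 90, labcols]
  expect_true(all(as.matrix(n90) <= as.matrix(n70)))
})

test_that("paired conformation-count comparison follows its conventions", {
  expect_equal(compare_conformation_counts_paired(1:5, 1:5)$p_value, 1)
  r <- compare_conformation_counts_paired(2:31, 1:30)
  expect_equal(r$p_value, 0)
  expect_match(r$flags, "degenerate")
  # Power at effect 0.5, sd 1, n = 400: essentially always rejects.
  withr::with_seed(29, {
    rejections <- vapply(1:25, function(i) {
      b <- rnorm(400, 10, 2)
      a <- b + rnorm(400, 0.5, 1)
      compare_conformation_counts_paired(a, b)$p_value < 0.05
    }, logical(1))
    expect_true(all(rejections))
  })
  expect_error(compare_conformation_counts_paired(1:3, 1:4),
               class = "kinconform_input_error")
  expect_error(compare_conformation_counts_paired(1, 1),
               class = "kinconform_input_error")
})

test_that("unique conformation counts ignore the Unassigned sink", {
  calls <- fake_calls(c("CIDI", "CODI", "Unassigned", "CIDI"),
                      kinase = c("k1", "k1", "k1", "k2"))
  u <- unique_conformation_counts(calls)
  expect_equal(u$n_conformations[u$kinase_id == "k1"], 2L)
  expect_equal(u$n_conformations[u$kinase_id == "k2"], 1L)
})
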