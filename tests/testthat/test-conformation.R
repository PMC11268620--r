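# Pseudo-dihedrals, geometric metrics and the six-state classification.

test_that("pseudo_dihedral reproduces the planar reference cases", {
  expect_equal(pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  # Right-handed positive: lifting the last point in +z from cis gives a
  # positive angle.
  expect_gt(pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0.5, 1, 0.5)), 0)
})

test_that("pseudo_dihedral agrees with the frame-based oracle on random quadruples", {
  withr::with_seed(7, {
    for (i in 1:200) {
      p <- matrix(rnorm(12, sd = 4), 4, 3)
      expect_equal(pseudo_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                   tolerance = 1e-11)
    }
  })
})

test_that("dihedral symmetry: reversal preserves, reflection flips the sign", {
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- matrix(rnorm(12, sd = 3), 4, 3)
      ang <- pseudo_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
      expect_equal(pseudo_dihedral(p[4, ], p[3, ], p[2, ], p[1, ]), ang,
                   tolerance = 1e-9)
      refl <- p
      refl[, 3] <- -refl[, 3]
      flipped <- pseudo_dihedral(refl[1, ], refl[2, ], refl[3, ], refl[4, ])
      if (abs(abs(ang) - 180) > 1e-9) {
        expect_equal(flipped, -ang, tolerance = 1e-9)
      }
    }
  })
})

test_that("degenerate dihedral geometry raises rather than returning 0", {
  p <- c(0, 0, 0)
  expect_error(pseudo_dihedral(p, p, c(1, 0, 0), c(2, 0, 0)),
               class = "kinconform_geometry_error")
  expect_error(
    pseudo_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    class = "kinconform_geometry_error"
  )
})

test_that("compute_geometry inverts the generator's construction exactly", {
  g <- list(dihedral_x = 55, dihedral_y = -120, d1 = 7, d2 = 15,
            salt_bridge = 3, loop_dist = 7)
  o <- make_structure(geometry = g, seed = 61)
  s <- o$structure
  m <- compute_geometry(s, detect_motifs(s))
  expect_equal(m$dihedral_x, 55, tolerance = 1e-6)
  expect_equal(m$dihedral_y, -120, tolerance = 1e-6)
  expect_equal(m$d1, 7, tolerance = 1e-6)
  expect_equal(m$d2, 15, tolerance = 1e-6)
  expect_equal(m$salt_bridge, 3, tolerance = 1e-6)
  expect_equal(m$loop_dist, 7, tolerance = 1e-6)
  # 7 A between HRD-2 and DFG+2 is the extended-loop regime.
  expect_identical(activation_loop_state(m$loop_dist), "extended")
})

test_that("Calpha-only structures fall back to Calpha anchors with flags", {
  o <- make_structure(target_label = "CIDI", seed = 71)
  s <- o$structure
  s$atoms <- s$atoms[s$atoms$name == "CA", , drop = FALSE]
  m <- compute_geometry(s, detect_motifs(s))
  expect_false(is.na(m$d1))
  expect_false(is.na(m$d2))
  expect_true(m$sb_fallback)
  expect_match(m$flags, "tip_fallback")
  expect_match(m$flags, "salt_bridge_ca_fallback")
  # alphaC call under the fallback criterion uses the wider Calpha cut.
  expect_identical(classify_alphaC(10, sb_fallback = TRUE), "in")
  expect_identical(classify_alphaC(10, sb_fallback = FALSE), "out")
})

test_that("DFG and alphaC state rules match their decision tables", {
  cfg <- conformation_config()
  expect_identical(classify_dfg(6, 15, cfg), "in")
  expect_identical(classify_dfg(15, 6, cfg), "out")
  expect_identical(classify_dfg(8, 8, cfg), "inter")
  expect_identical(classify_dfg(15, 15, cfg), "unassigned")
  expect_identical(classify_dfg(NA_real_, 6, cfg), "unassigned")
  # Boundaries: <= on both thresholds.
  expect_identical(classify_dfg(11, 11, cfg), "inter")
  expect_identical(classify_alphaC(3, FALSE, cfg), "in")
  expect_identical(classify_alphaC(9, FALSE, cfg), "out")
  expect_identical(classify_alphaC(4.5, FALSE, cfg), "in")
  expect_identical(classify_alphaC(NA_real_, FALSE, cfg), "undetermined")
  expect_identical(activation_loop_state(7, cfg), "extended")
  expect_identical(activation_loop_state(16, cfg), "folded")
  expect_identical(activation_loop_state(10, cfg), "extended")  # boundary
  expect_identical(activation_loop_state(NA_real_, cfg), "unavailable")
})

test_that("state combination maps onto the six-label vocabulary", {
  cs <- kinconform:::combine_states
  expect_identical(cs("in", "in"), "CIDI")
  expect_identical(cs("in", "out"), "CODI")
  expect_identical(cs("out", "in"), "CIDO")
  expect_identical(cs("out", "out"), "CODO")
  expect_identical(cs("inter", "in"), "DFGinter")
  expect_identical(cs("inter", "out"), "DFGinter")    # alphaC ignored
  expect_identical(cs("inter", "undetermined"), "DFGinter")
  expect_identical(cs("unassigned", "in"), "Unassigned")
  expect_identical(cs("in", "undetermined"), "Unassigned")
  expect_identical(cs("out", "undetermined"), "Unassigned")
})

test_that("all geometric metrics are rigid-motion invariant", {
  withr::with_seed(13, {
    for (lab in c("CIDI", "CIDO", "DFGinter")) {
      o <- make_structure(target_label = lab, seed = 300 + nchar(lab))
      s <- o$structure
      a <- detect_motifs(s)
      m0 <- compute_geometry(s, a)
      for (rep in 1:3) {
        s2 <- apply_rigid(s, random_rotation(), rnorm(3, sd = 30))
        m1 <- compute_geometry(s2, a)
        for (col in c("dihedral_x", "dihedral_y", "d1", "d2",
                      "salt_bridge", "loop_dist")) {
          expect_equal(m1[[col]], m0[[col]], tolerance = 1e-9)
        }
        expect_identical(call_conformation(s2, a)$label, o$label)
      }
    }
  })
})

test_that("conformation calls carry exactly one label and conserve counts", {
  ens <- make_ensemble(uniform_fractions(), n = 30, length = 80, seed = 17)
  calls <- classify_structures(ens$structures)
  expect_equal(nrow(calls), 30L)
  expect_true(all(calls$label[!calls$excluded] %in% conformation_labels()))
  d <- conformation_distribution(calls)
  expect_equal(sum(d$count) + unique(d$n_excluded), 30L)
})
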