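# Synthetic kinase geometries, model manifests and docking score tables
# with known ground truth, so every pipeline stage is testable without
# external downloads.
#
# Structures are built inside-out: the metric-defining atoms (DFG-Phe tip,
# beta3-Lys amine, alphaC-Glu carboxyl, the Calpha quadruples of both
# pseudo-dihedrals, and the two activation-loop Calphas) are placed
# analytically to realise the requested geometry exactly, and the remaining
# Calpha trace is threaded smoothly between those anchors. The classifier
# consumes only the planted atoms, so generator and classifier share one
# closed geometric contract; no physical realism is claimed for the
# connecting trace.

deg2rad <- function(x) x * pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension (NeRF) placement: position D such that |CD| = bond, the
# angle B-C-D equals `angle` and the torsion A-B-C-D equals `torsion`
# (degrees, IUPAC sign).
nerf_place <- function(a, b, c_, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unit(c_ - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.numeric(c_ + cbind(bc, m, n) %*% d2)
}

# Interior geometry boxes for each label: at least 1 A / 10 deg of margin
# from every decision threshold of `cfg`.
label_geometry_box <- function(label, cfg, margin = 1) {
  lo_in <- c(4, cfg$tau_d1 - margin)               # compatible with "short"
  hi_d1 <- c(cfg$tau_d1 + margin, cfg$tau_d1 + 7)  # clearly "long"
  hi_d2 <- c(cfg$tau_d2 + margin, cfg$tau_d2 + 7)
  lo_d2 <- c(4, cfg$tau_d2 - margin)
  sb_in <- c(2.6, cfg$tau_salt_bridge - margin)
  sb_out <- c(cfg$tau_salt_bridge + 1.5, cfg$tau_salt_bridge + 5.5)
  switch(label,
    CIDI = list(d1 = lo_in, d2 = hi_d2, sb = sb_in),
    CODI = list(d1 = lo_in, d2 = hi_d2, sb = sb_out),
    CIDO = list(d1 = hi_d1, d2 = lo_d2, sb = sb_in),
    CODO = list(d1 = hi_d1, d2 = lo_d2, sb = sb_out),
    DFGinter = list(d1 = lo_in, d2 = lo_d2, sb = NULL),
    Unassigned = list(d1 = hi_d1, d2 = hi_d2, sb = NULL),
    abort(sprintf("unknown label '%s'", label), class = "kinconform_input_error")
  )
}

runif1 <- function(range) stats::runif(1L, range[1], range[2])

sample_label_geometry <- function(label, cfg, margin = 1) {
  box <- label_geometry_box(label, cfg, margin)
  sb <- if (is.null(box$sb)) {
    if (stats::runif(1L) < 0.5) runif1(c(2.6, cfg$tau_salt_bridge - margin))
    else runif1(c(cfg$tau_salt_bridge + 1.5, cfg$tau_salt_bridge + 5.5))
  } else runif1(box$sb)
  loop_extended <- stats::runif(1L) < 0.7
  loop <- if (loop_extended) runif1(c(6, cfg$tau_loop - margin))
  else runif1(c(cfg$tau_loop + 2, cfg$tau_loop + 8))
  list(dihedral_x = stats::runif(1L, -170, 170),
       dihedral_y = stats::runif(1L, -170, 170),
       d1 = runif1(box$d1), d2 = runif1(box$d2),
       salt_bridge = sb, loop_dist = loop)
}

# Anchor indices (0-based) for a chain of `length` residues.
synthetic_anchor_indices <- function(length) {
  if (length < 60L) {
    abort("synthetic chain length must be >= 60", class = "kinconform_input_error")
  }
  idx_hrd <- as.integer(min(max(32L, floor(0.45 * length)), length - 26L))
  idx_dfg <- idx_hrd + 21L
  idx_lys <- idx_hrd - 28L
  idx_glu <- idx_lys + 12L
  list(lys = idx_lys, glu = idx_glu, hrd = idx_hrd, dfg = idx_dfg)
}

synthetic_sequence <- function(length, idx, dfg_seq = "DFG") {
  chars <- rep(c("A", "L"), length.out = length)
  chars[idx$lys + 1L] <- "K"
  chars[idx$glu + 1L] <- "E"
  chars[idx$hrd + 1L + 0:2] <- c("H", "R", "D")
  chars[idx$dfg + 1L + 0:2] <- strsplit(dfg_seq, "")[[1L]]
  chars
}

# Thread a smooth Calpha path through fixed anchors: linear interpolation
# between consecutive anchors plus a perpendicular sinusoidal bump (keeps
# intermediate triples off the anchor chord), and straight extensions with a
# gentle helix-like wobble before the first and after the last anchor.
thread_backbone <- function(n, fixed_idx, fixed_pos) {
  ord <- order(fixed_idx)
  fixed_idx <- fixed_idx[ord]
  fixed_pos <- fixed_pos[ord, , drop = FALSE]
  ca <- matrix(NA_real_, n, 3L)
  ca[fixed_idx + 1L, ] <- fixed_pos
  perp <- function(v) {
    w <- cross3(v, c(0, 0, 1))
    if (vnorm(w) < 1e-6) w <- cross3(v, c(1, 0, 0))
    unit(w)
  }
  for (k in seq_len(length(fixed_idx) - 1L)) {
    i <- fixed_idx[k]; j <- fixed_idx[k + 1L]
    gap <- j - i
    if (gap <= 1L) next
    P <- fixed_pos[k, ]; Q <- fixed_pos[k + 1L, ]
    w <- perp(Q - P)
    for (t in seq_len(gap - 1L)) {
      f <- t / gap
      ca[i + t + 1L, ] <- P + f * (Q - P) + 1.5 * sin(pi * f) * w
    }
  }
  first <- fixed_idx[1L]; last <- fixed_idx[length(fixed_idx)]
  if (first > 0L) {
    dirv <- unit(fixed_pos[1L, ] - fixed_pos[2L, ])
    w <- perp(dirv)
    for (t in seq_len(first)) {
      ca[first - t + 1L, ] <- fixed_pos[1L, ] + t * 3.8 * dirv +
        0.8 * sin(0.9 * t) * w
    }
  }
  if (last < n - 1L) {
    m <- length(fixed_idx)
    dirv <- unit(fixed_pos[m, ] - fixed_pos[m - 1L, ])
    w <- perp(dirv)
    for (t in seq_len(n - 1L - last)) {
      ca[last + t + 1L, ] <- fixed_pos[m, ] + t * 3.8 * dirv +
        0.8 * sin(0.9 * t) * w
    }
  }
  ca
}

#' Generate one synthetic kinase structure with known geometry
#'
#' Builds a Calpha trace with a planted Lys/Glu/HRD/DFG motif sequence and
#' side-chain pseudo-atoms (DFG-Phe CZ, beta3-Lys NZ, alphaC-Glu OE1/OE2)
#' placed so that the requested pseudo-dihedrals, DFG anchor distances, salt
#' bridge and activation-loop distance are realised exactly at zero noise;
#' isotropic Gaussian coordinate noise and per-residue pLDDT are then added.
#' Either give a `target_label`, in which case the geometry is drawn
#' uniformly from that label's interior region (at least 1 Angstrom / 10
#' degrees from every decision boundary of `cfg`), or give the full
#' `geometry` explicitly.
#'
#' @param target_label One of the six conformation labels, or `NULL`.
#' @param geometry Optional list with `dihedral_x`, `dihedral_y`, `d1`,
#'   `d2`, `salt_bridge`, `loop_dist` (degrees / Angstrom).
#' @param length Chain length in residues (>= 60, default 250).
#' @param noise_sigma Isotropic coordinate noise sd in Angstrom.
#' @param plddt_mean,plddt_sd Per-residue pLDDT distribution, clipped to
#'   \[0, 100\].
#' @param dfg_seq 3-mer planted at the DFG position (default `"DFG"`).
#' @param seed Optional RNG seed (same seed, same structure, bit for bit).
#' @param structure_id,kinase_id,group,source,msa_depth Metadata.
#' @param cfg A [conformation_config()]; the generator and classifier share
#'   its thresholds.
#' @return List with `structure` (a [kinase_structure()]), `label` (the true
#'   six-way label implied by the geometry), `loop_state`, and `metrics`
#'   (one-row tibble of the target geometry).
#' @export
make_structure <- function(target_label = NULL, geometry = NULL, length = 250,
                           noise_sigma = 0, plddt_mean = 90, plddt_sd = 3,
                           dfg_seq = "DFG", seed = NULL,
                           structure_id = "synth1", kinase_id = "kin1",
                           group = "unknown", source = "synthetic",
                           msa_depth = NULL, cfg = conformation_config()) {
  if (is.null(target_label) && is.null(geometry)) {
    abort("give target_label or an explicit geometry",
          class = "kinconform_input_error")
  }
  with_seed_maybe(seed, {
    g <- if (!is.null(geometry)) geometry
    else sample_label_geometry(target_label, cfg)
    need <- c("dihedral_x", "dihedral_y", "d1", "d2", "salt_bridge", "loop_dist")
    if (!all(need %in% names(g))) {
      abort(sprintf("geometry must provide: %s", paste(need, collapse = ", ")),
            class = "kinconform_input_error")
    }
    if (any(unlist(g[c("d1", "d2", "salt_bridge", "loop_dist")]) <= 0) ||
        any(unlist(g[c("d1", "d2", "salt_bridge", "loop_dist")]) > 60)) {
      abort("unrealizable geometry: distances must lie in (0, 60] Angstrom",
            class = "kinconform_input_error")
    }
    idx <- synthetic_anchor_indices(length)
    chars <- synthetic_sequence(length, idx, dfg_seq)

    # Metric-atom frame: Phe tip at the origin.
    cz <- c(0, 0, 0)
    ca_glu4 <- c(g$d1, 0, 0)
    u2 <- c(cos(deg2rad(110)), sin(deg2rad(110)), 0)
    nz <- g$d2 * u2
    oe1 <- nz + c(0, 0, g$salt_bridge)
    oe2 <- oe1 + c(0, 0, 2.2)
    ca_glu <- oe1 + 4 * unit(c(-0.5, 0.8, 0.1))
    ca_lys <- nz + 6 * unit(c(0.3, -0.9, 0.2))

    # DFG-window backbone (idx$dfg - 2 .. idx$dfg + 4) by torsion placement.
    s <- matrix(NA_real_, 7L, 3L)
    s[1L, ] <- c(0, 0, 0)
    s[2L, ] <- c(3.8, 0, 0)
    s[3L, ] <- s[2L, ] + 3.8 * c(-cos(deg2rad(112)), sin(deg2rad(112)), 0)
    s[4L, ] <- nerf_place(s[1L, ], s[2L, ], s[3L, ], 3.8, 112, g$dihedral_y)
    s[5L, ] <- nerf_place(s[2L, ], s[3L, ], s[4L, ], 3.8, 112, 60)
    s[6L, ] <- nerf_place(s[3L, ], s[4L, ], s[5L, ], 3.8, 112, g$dihedral_x)
    s[7L, ] <- nerf_place(s[4L, ], s[5L, ], s[6L, ], 3.8, 112, -60)
    phe_target <- cz + 4.2 * unit(c(-0.4, -0.8, 0.45))
    s <- sweep(s, 2L, phe_target - s[4L, ], "+")   # Phe Calpha onto target
    ca_hrd2 <- s[7L, ] + g$loop_dist * unit(c(0.1, 0.7, 0.7))

    fixed_idx <- c(idx$lys, idx$glu, idx$glu + 4L, idx$hrd - 2L,
                   (idx$dfg - 2L):(idx$dfg + 4L))
    fixed_pos <- rbind(ca_lys, ca_glu, ca_glu4, ca_hrd2, s)
    ca <- thread_backbone(length, fixed_idx, fixed_pos)

    atoms <- tibble(
      seq_index = c(seq_len(length) - 1L,
                    idx$dfg + 1L, idx$lys, idx$glu, idx$glu),
      name = c(rep("CA", length), "CZ", "NZ", "OE1", "OE2"),
      element = c(rep("C", length), "C", "N", "O", "O"),
      x = c(ca[, 1], cz[1], nz[1], oe1[1], oe2[1]),
      y = c(ca[, 2], cz[2], nz[2], oe1[2], oe2[2]),
      z = c(ca[, 3], cz[3], nz[3], oe1[3], oe2[3])
    )
    if (noise_sigma > 0) {
      atoms$x <- atoms$x + rnorm(nrow(atoms), 0, noise_sigma)
      atoms$y <- atoms$y + rnorm(nrow(atoms), 0, noise_sigma)
      atoms$z <- atoms$z + rnorm(nrow(atoms), 0, noise_sigma)
    }
    plddt <- pmin(100, pmax(0, rnorm(length, plddt_mean, plddt_sd)))
    residues <- tibble(seq_index = seq_len(length) - 1L,
                       auth_number = seq_len(length),
                       insert = "", aa = chars, plddt = plddt)
    st <- kinase_structure(structure_id = structure_id, kinase_id = kinase_id,
                           residues = residues, atoms = atoms, group = group,
                           source = source, msa_depth = msa_depth)
    true_label <- combine_states(classify_dfg(g$d1, g$d2, cfg),
                                 classify_alphaC(g$salt_bridge, FALSE, cfg))
    if (!is.null(target_label) && !identical(true_label, target_label)) {
      abort("geometry targets inconsistent with requested label",
            class = "kinconform_input_error")
    }
    list(structure = st, label = true_label,
         loop_state = activation_loop_state(g$loop_dist, cfg),
         metrics = as_tibble(g[need]))
  })
}

#' Generate a labelled ensemble of synthetic structures
#'
#' @param label_fractions Named numeric vector over (a subset of) the six
#'   labels, summing to 1; labels are assigned multinomially.
#' @param n Number of structures.
#' @param noise_sigma,length,plddt_mean,plddt_sd,cfg Passed to
#'   [make_structure()].
#' @param seed Optional RNG seed.
#' @return List with `structures` (list of [kinase_structure()], one kinase
#'   each) and `truth` (tibble `structure_id`, `kinase_id`, `label`,
#'   `loop_state` plus the target metrics).
#' @export
make_ensemble <- function(label_fractions, n, noise_sigma = 0, length = 250,
                          plddt_mean = 90, plddt_sd = 3, seed = NULL,
                          cfg = conformation_config()) {
  bad <- setdiff(names(label_fractions), conformation_labels())
  if (length(bad) || abs(sum(label_fractions) - 1) > 1e-8 ||
      any(label_fractions < 0)) {
    abort("label_fractions must be non-negative over the six labels and sum to 1",
          class = "kinconform_input_error")
  }
  assert_count(n, "n")
  with_seed_maybe(seed, {
    labels <- sample(names(label_fractions), n, replace = TRUE,
                     prob = label_fractions)
    out <- purrr::map(seq_len(n), function(i) {
      make_structure(target_label = labels[i], length = length,
                     noise_sigma = noise_sigma, plddt_mean = plddt_mean,
                     plddt_sd = plddt_sd,
                     structure_id = sprintf("synth%04d", i),
                     kinase_id = sprintf("kin%04d", i), cfg = cfg)
    })
    truth <- purrr::map_dfr(out, function(o) {
      dplyr::bind_cols(tibble(structure_id = o$structure$structure_id,
                              kinase_id = o$structure$kinase_id,
                              label = o$label, loop_state = o$loop_state),
                       o$metrics)
    })
    list(structures = purrr::map(out, "structure"), truth = truth)
  })
}

default_depth_probs <- function(depth) {
  t <- (log2(depth) - 1) / 8            # 0 at depth 2, 1 at depth 512
  t <- min(max(t, 0), 1)
  p <- c(CIDI = 0.40 + 0.35 * t, CODI = 0.20 - 0.08 * t,
         CIDO = 0.12 - 0.06 * t, CODO = 0.06 - 0.04 * t,
         DFGinter = 0.06 - 0.04 * t)
  c(p, Unassigned = 1 - sum(p))
}

#' Generate a synthetic model manifest over MSA depths
#'
#' Emulates the shape of a prediction campaign: up to `models_per_kinase`
#' models per kinase at each MSA depth, per-depth conformation-label
#' probabilities (defaulting to less conformational diversity at deeper
#' alignments) and model confidences, a fraction of kinases whose anchoring
#' fails (excluded everywhere and counted), a fraction of kinases with no
#' experimentally observed reference conformations, and optional per-depth
#' kinase dropouts (prediction failures).
#'
#' @param n_kinases Number of kinases (default 497).
#' @param depths MSA depths (default `c(2, 4, 8, 16, 32, 128, 512)`).
#' @param models_per_kinase Models per kinase per depth (default 5).
#' @param label_probs Optional function `depth -> named probability vector`
#'   over the six labels; default [default_depth_probs].
#' @param plddt_params Optional function `depth -> c(mean, sd)` of the
#'   model-level mean pLDDT; default mean rising from 72 (depth 2) to 88
#'   (depth 512), sd 6.
#' @param fail_fraction Fraction of kinases marked anchoring-failed
#'   (default 12/497).
#' @param empty_reference_fraction Fraction of kinases with no reference
#'   structure (default 0.15).
#' @param dropped Optional named integer vector: number of otherwise-valid
#'   kinases whose models are missing at the named depth (e.g.
#'   `c("512" = 1)`).
#' @param seed Optional RNG seed.
#' @return List with `model_calls` (call-shaped tibble incl. excluded rows),
#'   `reference_calls` (tibble `kinase_id`, `label`) and `failed_kinases`.
#' @export
make_model_manifest <- function(n_kinases = 497,
                                depths = c(2, 4, 8, 16, 32, 128, 512),
                                models_per_kinase = 5,
                                label_probs = NULL, plddt_params = NULL,
                                fail_fraction = 12 / 497,
                                empty_reference_fraction = 0.15,
                                dropped = NULL, seed = NULL) {
  assert_count(n_kinases, "n_kinases")
  assert_count(models_per_kinase, "models_per_kinase")
  label_probs <- label_probs %||% default_depth_probs
  plddt_params <- plddt_params %||% function(depth) {
    t <- min(max((log2(depth) - 1) / 8, 0), 1)
    c(72 + 16 * t, 6)
  }
  with_seed_maybe(seed, {
    kin <- sprintf("kin%04d", seq_len(n_kinases))
    n_fail <- round(fail_fraction * n_kinases)
    failed <- if (n_fail > 0) sample(kin, n_fail) else character(0)
    valid <- setdiff(kin, failed)
    model_calls <- purrr::map_dfr(depths, function(d) {
      pr <- label_probs(d)[conformation_labels()]
      pp <- plddt_params(d)
      drop_n <- if (!is.null(dropped) && as.character(d) %in% names(dropped)) {
        dropped[[as.character(d)]]
      } else 0L
      present <- if (drop_n > 0) valid[-seq_len(drop_n)] else valid
      ids <- c(rep(present, each = models_per_kinase),
               rep(failed, each = models_per_kinase))
      excl <- c(rep(FALSE, length(present) * models_per_kinase),
                rep(TRUE, length(failed) * models_per_kinase))
      n_cls <- sum(!excl)
      tibble(
        structure_id = sprintf("%s_d%d_m%d", ids, d,
                               rep(seq_len(models_per_kinase),
                                   times = length(ids) / models_per_kinase)),
        kinase_id = ids, group = "unknown", source = "af2",
        msa_depth = as.integer(d),
        label = dplyr::if_else(excl, NA_character_,
                               sample(names(pr), length(ids), replace = TRUE,
                                      prob = pr)),
        mean_plddt = dplyr::if_else(excl, NA_real_,
                                    pmin(100, pmax(0, rnorm(length(ids),
                                                            pp[1], pp[2])))),
        excluded = excl,
        exclude_reason = dplyr::if_else(excl, "anchoring failure", NA_character_)
      )
    })
    ref_probs <- c(CIDI = 0.5, CODI = 0.2, CIDO = 0.15, CODO = 0.05,
                   DFGinter = 0.05, Unassigned = 0.05)
    reference_calls <- purrr::map_dfr(valid, function(k) {
      if (stats::runif(1L) < empty_reference_fraction) return(NULL)
      n_lab <- sample(1:3, 1L, prob = c(0.6, 0.3, 0.1))
      tibble(kinase_id = k,
             label = sample(names(ref_probs), n_lab, prob = ref_probs))
    })
    list(model_calls = model_calls, reference_calls = reference_calls,
         failed_kinases = failed)
  })
}

#' Generate a synthetic docking score table with known expected AUC
#'
#' Actives and decoys are drawn from Normal score distributions; for
#' lower-better scores the closed-form expected enrichment AUC is
#' `100 * pnorm((mu_decoy - mu_active) / (sigma * sqrt(2)))` (the
#' probability an active outranks a decoy; with several poses per compound
#' the best-pose reduction shifts the realised AUC slightly).
#'
#' @param n_actives,n_decoys Compound counts (the conventional benchmark
#'   shape is 50 actives with 50 decoys each, i.e. 2,500 decoys).
#' @param mu_active,mu_decoy,sigma Score distribution parameters.
#' @param direction `"lower_better"` (default) or `"higher_better"`.
#' @param poses_per_compound Poses drawn per compound (>= 1).
#' @param model_id Model identifier stamped on the records.
#' @param seed Optional RNG seed.
#' @return List with `records` (tibble `model_id`, `compound_id`, `label`,
#'   `score`, `pose_rank`) and `expected_auc`.
#' @export
make_score_table <- function(n_actives = 50, n_decoys = 2500,
                             mu_active = -8, mu_decoy = -6, sigma = 1,
                             direction = c("lower_better", "higher_better"),
                             poses_per_compound = 1, model_id = "model1",
                             seed = NULL) {
  direction <- match.arg(direction)
  assert_count(n_actives, "n_actives")
  assert_count(n_decoys, "n_decoys")
  assert_count(poses_per_compound, "poses_per_compound")
  if (sigma <= 0) {
    abort("sigma must be positive", class = "kinconform_input_error")
  }
  with_seed_maybe(seed, {
    ids <- c(sprintf("act%04d", seq_len(n_actives)),
             sprintf("dec%04d", seq_len(n_decoys)))
    lab <- rep(c("active", "decoy"), c(n_actives, n_decoys))
    mu <- rep(c(mu_active, mu_decoy), c(n_actives, n_decoys))
    records <- tibble(
      model_id = model_id,
      compound_id = rep(ids, each = poses_per_compound),
      label = rep(lab, each = poses_per_compound),
      score = rnorm(length(ids) * poses_per_compound,
                    rep(mu, each = poses_per_compound), sigma),
      pose_rank = rep(seq_len(poses_per_compound), times = length(ids))
    )
    delta <- if (direction == "lower_better") mu_decoy - mu_active
    else mu_active - mu_decoy
    list(records = records,
         expected_auc = 100 * pnorm(delta / (sigma * sqrt(2))))
  })
}
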