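# Independent oracles and small fixture builders used across the suite.

# Frame-based torsion oracle, derived independently of the cross-product
# formula in pseudo_dihedral(): build an orthonormal frame on the central
# bond and read the angle from projected 2-D coordinates.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  e1 <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * e1) * e1   # p1 displacement off the bond
  v <- (p4 - p3) - sum((p4 - p3) * e1) * e1
  ex <- u / sqrt(sum(u^2))                    # cis reference direction
  ey <- c(e1[2] * ex[3] - e1[3] * ex[2],
          e1[3] * ex[1] - e1[1] * ex[3],
          e1[1] * ex[2] - e1[2] * ex[1])
  ang <- atan2(sum(v * ey), sum(v * ex)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Two-sided Fisher p for a 2x2 table by explicit hypergeometric enumeration
# over all tables with the observed margins, using the standard relative
# tolerance when collecting tables as extreme as the observed one.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Uniformly random proper rotation matrix (QR of a Gaussian matrix with sign
# correction).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(s, R, tvec) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s$atoms$x <- xyz[, 1] + tvec[1]
  s$atoms$y <- xyz[, 2] + tvec[2]
  s$atoms$z <- xyz[, 3] + tvec[3]
  s
}

# Minimal hand-built structure from a sequence string: Calpha atoms on a
# gentle helix (non-collinear, ~3.8 A spacing).
toy_structure <- function(seq_string, plddt = NA_real_, structure_id = "toy",
                          kinase_id = "toyk", source = "synthetic") {
  n <- nchar(seq_string)
  i <- seq_len(n)
  residues <- tibble::tibble(seq_index = i - 1L, auth_number = i, insert = "",
                             aa = strsplit(seq_string, "")[[1]],
                             plddt = rep(plddt, length.out = n))
  atoms <- tibble::tibble(seq_index = i - 1L, name = "CA", element = "C",
                          x = 2.28 * cos(i), y = 2.28 * sin(i), z = 1.9 * i)
  kinconform::kinase_structure(structure_id, kinase_id, residues, atoms,
                               source = source)
}

# TM-score from the single one-shot global Kabsch superposition only: the
# baseline the full search must dominate.
single_kabsch_tm <- function(model, other) {
  rm_ <- model$residues; ro <- other$residues
  common <- intersect(rm_$auth_number, ro$auth_number)
  am <- model$atoms[model$atoms$name == "CA", ]
  ao <- other$atoms[other$atoms$name == "CA", ]
  A <- as.matrix(am[match(match(common, rm_$auth_number) - 1L, am$seq_index),
                    c("x", "y", "z")])
  B <- as.matrix(ao[match(match(common, ro$auth_number) - 1L, ao$seq_index),
                    c("x", "y", "z")])
  ok <- !is.na(rowSums(A)) & !is.na(rowSums(B))
  A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  k <- kinconform::kabsch_superpose(A, B)
  fit <- sweep(B %*% k$rotation, 2, k$translation, "+")
  l_ref <- nrow(rm_)
  d0 <- max(1.24 * (l_ref - 15)^(1 / 3) - 1.8, 0.5)
  sum(1 / (1 + rowSums((fit - A)^2) / d0^2)) / l_ref
}

# Hinge-perturbed copy: rotate the C-terminal part of the chain about an
# axis through a pivot residue, emulating a sub-domain motion.
hinge_perturb <- function(s, pivot_frac = 0.55, angle = 25 * pi / 180) {
  ca <- s$atoms$name == "CA"
  n <- nrow(s$residues)
  pivot_idx <- floor(pivot_frac * n)
  pivot <- as.numeric(unlist(
    s$atoms[s$atoms$name == "CA" & s$atoms$seq_index == pivot_idx,
            c("x", "y", "z")]))
  axis <- c(0, 0, 1)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  move <- s$atoms$seq_index > pivot_idx
  xyz <- as.matrix(s$atoms[move, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
  s$atoms$x[move] <- xyz[, 1]
  s$atoms$y[move] <- xyz[, 2]
  s$atoms$z[move] <- xyz[, 3]
  s
}

uniform_fractions <- function() {
  stats::setNames(rep(1 / 6, 6), kinconform::conformation_labels())
}
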