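# Shared fixtures (built in code, no files) and independent oracles.

# --- independent oracles -------------------------------------------------

# Brute-force cyclic offset: argmin over {j-i, j-i+L, j-i-L} by absolute
# value, ties resolved to the positive candidate.
oracle_cyclic_offset <- function(i, j, L) {
  cand <- c(j - i, j - i + L, j - i - L)
  best <- cand[order(abs(cand), -cand)][1]
  best
}

# Monte-Carlo rotation-search superposition: minimum rmsd over n_rot
# sampled rotations, centroids removed. The search is staged: a uniform
# sweep of SO(3) (normalized quaternions) followed by progressively
# narrower random sweeps around the incumbent best, all within the same
# rotation budget. Independent of the analytic Kabsch path.
mc_min_rmsd <- function(X, Y, n_rot = 100000, seed = 1) {
  set.seed(seed)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  C <- crossprod(Yc, Xc)  # 3x3 cross-covariance
  const <- sum(Xc^2) + sum(Yc^2)
  n <- nrow(X)

  quat_to_flat <- function(q) {
    q <- q / sqrt(rowSums(q^2))
    w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
    cbind(
      1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
      2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
      2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
    )
  }
  rmsd_of <- function(Rf) {
    tr <- as.vector(Rf %*% as.vector(C))
    sqrt(pmax(0, const - 2 * tr) / n)
  }

  # Hamilton product of quaternion rows `a` with one quaternion `b`
  qmul <- function(a, b) {
    cbind(a[, 1] * b[1] - a[, 2] * b[2] - a[, 3] * b[3] - a[, 4] * b[4],
          a[, 1] * b[2] + a[, 2] * b[1] + a[, 3] * b[4] - a[, 4] * b[3],
          a[, 1] * b[3] - a[, 2] * b[4] + a[, 3] * b[1] + a[, 4] * b[2],
          a[, 1] * b[4] + a[, 2] * b[3] - a[, 3] * b[2] + a[, 4] * b[1])
  }

  stages <- c(0.4, 0.2, 0.2, 0.1, 0.1) * n_rot
  sigmas <- c(NA, 0.2, 0.05, 0.01, 0.002)  # radians; NA = uniform
  best_rmsd <- Inf
  best_q <- c(1, 0, 0, 0)
  for (s in seq_along(stages)) {
    m <- stages[s]
    if (is.na(sigmas[s])) {
      q <- matrix(rnorm(m * 4), m, 4)
      q <- q / sqrt(rowSums(q^2))
    } else {
      # small random rotations composed with the incumbent best
      half <- abs(rnorm(m, 0, sigmas[s])) / 2
      ax <- matrix(rnorm(m * 3), m, 3)
      ax <- ax / sqrt(rowSums(ax^2))
      q <- qmul(cbind(cos(half), sin(half) * ax), best_q)
    }
    vals <- rmsd_of(quat_to_flat(q))
    i <- which.min(vals)
    if (vals[i] < best_rmsd) {
      best_rmsd <- vals[i]
      best_q <- q[i, ]
    }
  }
  best_rmsd
}

# Closed-form buried area of two intersecting probe-expanded spheres
# (spherical caps), for the contact_surface oracle.
two_sphere_buried <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  if (d >= R1 + R2) return(0)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (2 * pi * R1 * h1 + 2 * pi * R2 * h2) / 2
}

# --- structure fixtures --------------------------------------------------

helical_torsions <- function(L) {
  torsion_set(rep(-57, L), rep(-47, L), rep(180, L))
}

# deterministic closed macrocycle
closed_fixture <- function(L = 12, seed = 11) {
  ens <- generate_ensemble(generator_config(length = L, seed = seed, n = 1))
  ens$structures[[1]]
}

random_rotation_fix <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Small synthetic target chain: backbone "residues" laid on a helical
# arc (non-collinear, so superpositions are well determined).
synthetic_target_atoms <- function(n = 30, chain = "B", origin = c(20, 0, 0),
                                   radius = 8, rise = 1.5, turn = 0.35) {
  rows <- lapply(seq_len(n), function(r) {
    base <- origin + c(radius * cos(r * turn), radius * sin(r * turn),
                       rise * r)
    data.frame(
      chain = chain, resno = r, resid = "ALA",
      elety = c("N", "CA", "C", "O"),
      x = base[1] + c(-1.2, 0, 1.2, 1.6),
      y = base[2] + c(0.3, 0, 0.4, 1.4),
      z = base[3] + c(0.2, 0, -0.2, 0.1),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# complex of a closed macrocycle placed near a synthetic target
synthetic_complex <- function(L = 12, seed = 11, offset = c(12, 0, 0)) {
  mc <- closed_fixture(L, seed)
  mc <- rigid_transform(mc, diag(3), offset)
  make_complex(mc, synthetic_target_atoms(origin = c(20, 0, 0)))
}

# Idealized phenylalanine-like residue with an explicit side chain
# (approximate ring geometry; self-consistent for SASA ratio tests).
phe_residue_atoms <- function(chain = "A", resno = 1, origin = c(0, 0, 0)) {
  ring <- sapply(0:5, function(k) {
    th <- k * pi / 3
    c(1.4 * cos(th), 1.4 * sin(th), 0)
  })
  xyz <- rbind(
    N = c(-2.6, 1.2, 0.4), CA = c(-2.0, 0, 0), C = c(-2.7, -1.2, -0.5),
    O = c(-3.9, -1.3, -0.4),
    CB = c(-0.6, 0, 0.4), CG = c(0.9, 0, 0),
    CD1 = t(ring)[2, ], CD2 = t(ring)[6, ],
    CE1 = t(ring)[3, ], CE2 = t(ring)[5, ], CZ = t(ring)[4, ]
  )
  xyz[7:11, ] <- xyz[7:11, ] + matrix(rep(c(0.9, 0, 0), 5), 5, byrow = TRUE)
  data.frame(
    chain = chain, resno = resno, resid = "PHE",
    elety = rownames(xyz),
    element = ifelse(rownames(xyz) %in% c("N"), "N",
                     ifelse(rownames(xyz) == "O", "O", "C")),
    x = xyz[, 1] + origin[1], y = xyz[, 2] + origin[2],
    z = xyz[, 3] + origin[3],
    stringsAsFactors = FALSE
  )
}

# tight cage of dummy atoms enclosing a point, for burial fixtures
cage_atoms <- function(center = c(0, 0, 0), radius = 3.0, n = 60,
                       chain = "Z", resno_start = 900) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  data.frame(
    chain = chain, resno = resno_start + i, resid = "GLY", elety = "CA",
    element = "C",
    x = center[1] + radius * r * cos(phi),
    y = center[2] + radius * r * sin(phi),
    z = center[3] + radius * z,
    stringsAsFactors = FALSE
  )
}
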