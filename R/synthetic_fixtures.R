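# Seeded generators: closed macrocycle backbones with controllable
# secondary-structure content, perturbed structure pairs, and metric
# tables with planted pass/fail structure. Every output is a pure
# function of (config, seed).

.basin_centers <- list(
  helical = c(phi = -57, psi = -47),
  strand = c(phi = -120, psi = 120)
)
# loop basin: 50/50 mixture of a polyproline-like and a left-handed
# center with its own 25 degree spread (a pragmatic stand-in for
# irregular loop torsions)
.loop_centers <- matrix(c(-80, 150, 60, 40), 2, 2, byrow = TRUE,
                        dimnames = list(NULL, c("phi", "psi")))
.loop_jitter <- 25

#' Generator configuration for synthetic macrocycles
#'
#' @param length Residue count (>= 3).
#' @param basin_weights Numeric length-3 vector of (helical, strand,
#'   loop) basin probabilities, non-negative, summing to 1.
#' @param jitter Torsion jitter standard deviation in degrees for the
#'   helical/strand basins (the loop basin uses its own 25 degree
#'   spread).
#' @param seed Integer RNG seed.
#' @param n Ensemble size for [generate_ensemble()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(length = 12,
                             basin_weights = c(helical = 0.5,
                                               strand = 0.2, loop = 0.3),
                             jitter = 10, seed = 1, n = 10) {
  if (length < 3) stop("`length` must be >= 3")
  if (base::length(basin_weights) != 3 || any(basin_weights < 0))
    stop("`basin_weights` must be 3 non-negative weights")
  if (abs(sum(basin_weights) - 1) > 1e-9)
    stop("`basin_weights` must sum to 1")
  names(basin_weights) <- c("helical", "strand", "loop")
  structure(list(length = as.integer(length),
                 basin_weights = basin_weights,
                 jitter = jitter, seed = as.integer(seed),
                 n = as.integer(n)),
            class = "generator_config")
}

#' Sample per-residue torsions from Ramachandran basins
#'
#' Each residue's basin is drawn from the configured weights; torsions
#' are the basin center (helical (-57, -47), strand (-120, 120), loop a
#' broad left/right mixture) plus Gaussian jitter; omega is 180
#' (trans). The drawn basin per residue is attached as attribute
#' `"basin"`.
#'
#' @param config A [generator_config()].
#' @return A [torsion_set()] of `config$length` residues.
#' @export
sample_torsions <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  .sample_torsions_impl(config)
}

.sample_torsions_impl <- function(config) {
  L <- config$length
  basin <- sample(c("helical", "strand", "loop"), L, replace = TRUE,
                  prob = config$basin_weights)
  phi <- psi <- numeric(L)
  for (r in seq_len(L)) {
    if (basin[r] == "loop") {
      ctr <- .loop_centers[sample(2, 1), ]
      sdv <- .loop_jitter
    } else {
      ctr <- .basin_centers[[basin[r]]]
      sdv <- config$jitter
    }
    phi[r] <- wrap_angle(ctr[["phi"]] + rnorm(1, 0, sdv))
    psi[r] <- wrap_angle(ctr[["psi"]] + rnorm(1, 0, sdv))
  }
  out <- torsion_set(phi, psi, rep(180, L), cyclic = TRUE)
  attr(out, "basin") <- basin
  out
}

# Anchor RMSD of the virtual closing residue onto residue 1: the
# closure gap driven to zero by CCD.
.ccd_gap <- function(vatoms, targets) {
  sqrt(mean(rowSums((vatoms - targets)^2)))
}

#' Close a macrocycle ring by cyclic coordinate descent
#'
#' Iteratively adjusts one backbone torsion at a time (psi of residues
#' 1..L, phi of residues 2..L and the virtual closing phi), each time
#' applying the closed-form rotation that best superposes a virtual copy
#' of residue 1 - built beyond residue L with ideal peptide geometry and
#' trans omega - onto the actual residue 1. When the virtual atoms land
#' on residue 1, the closing C(L)-N(1) bond has ideal geometry by
#' construction. The closure gap (anchor r.m.s.d.) is non-increasing
#' across updates.
#'
#' @param open_structure An open [macrocycle_structure()] from
#'   [build_from_torsions()], length >= 5.
#' @param max_iter Maximum number of full sweeps over the torsions.
#' @param tol Convergence tolerance on the closure gap (Angstrom).
#' @return A cyclic [macrocycle_structure()] with attributes
#'   `converged` (logical), `gap` (final anchor r.m.s.d.) and
#'   `gap_trace` (per-sweep gaps, non-increasing).
#' @export
ccd_close <- function(open_structure, max_iter = 500, tol = 0.08) {
  stopifnot(inherits(open_structure, "macrocycle_structure"))
  L <- n_residues(open_structure)
  if (L < 5) stop("ring closure needs at least 5 residues")
  g <- .bb_geom
  co <- open_structure$coords

  # flat backbone coordinate matrix: rows 3(r-1)+1..3 are N, CA, C of
  # residue r; three extra rows hold the virtual closing residue
  X <- matrix(NA_real_, 3 * L + 3, 3)
  for (r in seq_len(L)) {
    X[3 * r - 2, ] <- co[r, "N", ]
    X[3 * r - 1, ] <- co[r, "CA", ]
    X[3 * r, ] <- co[r, "C", ]
  }
  # Virtual-residue seeding: prefer the torsions a previous closure
  # stored; otherwise measure them against residue 1 (for an
  # already-closed ring the virtual copy then lands on residue 1, for an
  # open chain this is only an initialization)
  vt <- attr(open_structure, "virtual_torsions")
  if (is.null(vt)) {
    seed_psi <- attr(open_structure, "seed_psi_L")
    if (is.null(seed_psi) || is.na(seed_psi))
      seed_psi <- dihedral(X[3 * L - 2, ], X[3 * L - 1, ], X[3 * L, ], X[1, ])
    seed_phi <- dihedral(X[3 * L, ], X[1, ], X[2, ], X[3, ])
    vt <- c(psi = seed_psi, phi = seed_phi)
  }
  X[3 * L + 1, ] <- place_atom(X[3 * L - 2, ], X[3 * L - 1, ], X[3 * L, ],
                               g$b_c_n, g$a_ca_c_n, vt[["psi"]])
  X[3 * L + 2, ] <- place_atom(X[3 * L - 1, ], X[3 * L, ], X[3 * L + 1, ],
                               g$b_n_ca, g$a_c_n_ca, 180)
  X[3 * L + 3, ] <- place_atom(X[3 * L, ], X[3 * L + 1, ], X[3 * L + 2, ],
                               g$b_ca_c, g$a_n_ca_c, vt[["phi"]])
  targets <- X[1:3, ]
  anchor_idx <- (3 * L + 1):(3 * L + 3)

  # rotatable axes: (from atom, to atom, first moving atom index)
  axes <- list()
  for (r in seq_len(L)) {
    if (r >= 2)  # phi_r: N_r -> CA_r moves C_r onward
      axes[[length(axes) + 1L]] <- c(3 * r - 2, 3 * r - 1, 3 * r)
    # psi_r: CA_r -> C_r moves N_{r+1} onward
    axes[[length(axes) + 1L]] <- c(3 * r - 1, 3 * r, 3 * r + 1)
  }
  # virtual phi: vN -> vCA moves vC
  axes[[length(axes) + 1L]] <- c(3 * L + 1, 3 * L + 2, 3 * L + 3)

  gap <- .ccd_gap(X[anchor_idx, ], targets)
  trace <- gap
  iter <- 0L
  while (gap > tol && iter < max_iter) {
    iter <- iter + 1L
    for (ax in axes) {
      move <- ax[3]:(3 * L + 3)
      mv_anchor <- intersect(move, anchor_idx)
      if (!length(mv_anchor)) next
      p <- X[ax[1], ]
      u <- .unit(X[ax[2], ] - p)
      a <- 0; b <- 0
      for (k in mv_anchor) {
        f <- targets[match(k, anchor_idx), ] - p
        m <- X[k, ] - p
        o <- sum(m * u) * u
        rvec <- m - o
        rlen <- .vnorm(rvec)
        if (rlen < 1e-9) next
        sh <- rvec / rlen
        th <- .cross(u, sh)
        fp <- f - o
        a <- a + rlen * sum(fp * sh)
        b <- b + rlen * sum(fp * th)
      }
      if (a == 0 && b == 0) next
      theta <- atan2(b, a)
      R <- rotation_about_axis(u, theta)
      X[move, ] <- sweep(sweep(X[move, , drop = FALSE], 2, p) %*% t(R),
                         2, p, `+`)
    }
    gap <- .ccd_gap(X[anchor_idx, ], targets)
    trace <- c(trace, gap)
  }

  for (r in seq_len(L)) {
    co[r, "N", ] <- X[3 * r - 2, ]
    co[r, "CA", ] <- X[3 * r - 1, ]
    co[r, "C", ] <- X[3 * r, ]
  }
  closed <- macrocycle_structure(co[, c("N", "CA", "C"), , drop = FALSE],
                                 sequence = open_structure$sequence,
                                 cyclic = TRUE)
  # rebuild carbonyl O from the now-defined (wrapped) psi torsions
  tor <- measure_torsions(closed)
  cof <- closed$coords
  for (r in seq_len(L))
    cof[r, "O", ] <- place_atom(cof[r, "N", ], cof[r, "CA", ], cof[r, "C", ],
                                g$b_c_o, g$a_ca_c_o,
                                wrap_angle(tor$psi[r] + 180))
  closed$coords <- cof
  attr(closed, "converged") <- gap <= tol
  attr(closed, "gap") <- gap
  attr(closed, "gap_trace") <- trace
  # remember the converged virtual-frame torsions so a rerun rebuilds
  # the same anchors and sees the ring as the fixed point it is
  attr(closed, "virtual_torsions") <- c(
    psi = dihedral(X[3 * L - 2, ], X[3 * L - 1, ], X[3 * L, ],
                   X[3 * L + 1, ]),
    phi = dihedral(X[3 * L, ], X[3 * L + 1, ], X[3 * L + 2, ],
                   X[3 * L + 3, ]))
  closed
}

#' Add isotropic Gaussian coordinate noise to a structure
#'
#' Adds seeded independent Gaussian noise (standard deviation
#' `amplitude` per coordinate) to every stored atom.
#'
#' @param structure A [macrocycle_structure()].
#' @param amplitude Noise standard deviation per coordinate (Angstrom,
#'   >= 0).
#' @param seed Integer RNG seed.
#' @return The perturbed structure.
#' @export
perturb <- function(structure, amplitude, seed = 1) {
  stopifnot(inherits(structure, "macrocycle_structure"))
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (amplitude == 0) return(structure)
  set.seed(seed)
  co <- structure$coords
  noise <- array(rnorm(length(co), 0, amplitude), dim = dim(co))
  noise[is.na(co)] <- NA
  structure$coords <- co + noise
  structure
}

#' Generate an ensemble of closed macrocycle backbones
#'
#' Draws `config$n` torsion sets, builds open backbones with ideal
#' geometry and closes each ring by CCD. Non-converged members are
#' flagged in the manifest, not dropped.
#'
#' @param config A [generator_config()].
#' @return List with `structures` (list of cyclic
#'   [macrocycle_structure()]s) and `manifest` (seed, config echo,
#'   per-member convergence and gap, convergence rate).
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  structures <- vector("list", config$n)
  converged <- logical(config$n)
  gaps <- numeric(config$n)
  for (k in seq_len(config$n)) {
    tor <- .sample_torsions_impl(config)
    closed <- ccd_close(build_from_torsions(tor))
    structures[[k]] <- closed
    converged[k] <- attr(closed, "converged")
    gaps[k] <- attr(closed, "gap")
  }
  names(structures) <- sprintf("mc_%03d", seq_len(config$n))
  manifest <- list(
    seed = config$seed,
    config = list(length = config$length,
                  basin_weights = as.list(config$basin_weights),
                  jitter = config$jitter, n = config$n),
    converged = converged, gap = gaps,
    convergence_rate = mean(converged)
  )
  list(structures = structures, manifest = manifest)
}

#' Plant a clustered ensemble of macrocycle backbones
#'
#' Draws `k` mutually distinct template backbones (templates with
#' pairwise TM-score above `template_tm_max` to an accepted template are
#' redrawn, so the planted clusters are separated at the clustering
#' threshold) and emits `copies` perturbed copies of each.
#'
#' @param k Number of planted clusters.
#' @param copies Perturbed copies per template.
#' @param length Macrocycle length.
#' @param amplitude Perturbation noise (Angstrom per coordinate).
#' @param seed Integer RNG seed.
#' @param template_tm_max Maximum TM-score allowed between accepted
#'   templates.
#' @return List with `structures` (k * copies perturbed structures),
#'   `truth` (template index per structure) and `templates`.
#' @export
plant_clustered_ensemble <- function(k, copies = 10, length = 24,
                                     amplitude = 0.3, seed = 1,
                                     template_tm_max = 0.45) {
  set.seed(seed)
  templates <- list()
  attempts <- 0L
  cfg_seed <- seed
  while (base::length(templates) < k) {
    attempts <- attempts + 1L
    if (attempts > 50L * k) stop("could not plant distinct templates")
    cfg_seed <- cfg_seed + 1L
    w <- runif(3); w <- w / sum(w)
    cfg <- generator_config(length = length, basin_weights = w,
                            jitter = 12, seed = cfg_seed, n = 1)
    cand <- generate_ensemble(cfg)$structures[[1]]
    if (!attr(cand, "converged")) next
    ok <- all(vapply(templates, function(t)
      tm_score(t, cand)$score < template_tm_max, logical(1)))
    if (ok) templates[[base::length(templates) + 1L]] <- cand
  }
  structures <- list()
  truth <- integer(0)
  for (i in seq_len(k)) {
    for (cpy in seq_len(copies)) {
      structures[[base::length(structures) + 1L]] <-
        perturb(templates[[i]], amplitude,
                seed = (seed %% 1000000L) * 1009L + i * 100L + cpy)
      truth <- c(truth, i)
    }
  }
  names(structures) <- sprintf("t%02d_c%02d", truth,
                               stats::ave(truth, truth, FUN = seq_along))
  list(structures = structures, truth = truth, templates = templates)
}

#' Synthesize a metric table with a planted survivor count
#'
#' Constructs `n` design records of which exactly `planted_pass_count`
#' satisfy every threshold of `preset` (sampled strictly inside the pass
#' region) while the remainder violate at least one randomly chosen
#' tested metric (sampled strictly outside). Rows are shuffled by the
#' seed.
#'
#' @param n Number of designs.
#' @param preset A [campaign_preset()] with all thresholds set.
#' @param planted_pass_count Number of passing rows (0..n).
#' @param seed Integer RNG seed.
#' @param path Optional CSV output path (written via [write_metrics()]).
#' @return Design-record data frame (invisibly writes `path` when
#'   given).
#' @export
synth_metric_table <- function(n, preset, planted_pass_count, seed = 1,
                               path = NULL) {
  stopifnot(inherits(preset, "campaign_preset"))
  if (planted_pass_count < 0 || planted_pass_count > n)
    stop("`planted_pass_count` must be in 0..n")
  thr <- preset$thresholds
  if (any(vapply(thr, is.na, logical(1))))
    stop("preset has unset thresholds; the pass region is undefined")
  set.seed(seed)
  metrics <- .required_metrics(preset)

  sample_pass <- function(m) {
    switch(m,
           ipae = runif(1, 0.3, 0.95) * thr$ipae_max,
           ddg = thr$ddg_max - runif(1, 2, 30),
           sap = runif(1, 0.2, 0.95) * thr$sap_max,
           cms = thr$cms_min + runif(1, 20, 250),
           rmsd_pred = runif(1, 0.2, 0.9) * thr$rmsd_pred_max)
  }
  sample_fail <- function(m) {
    switch(m,
           ipae = thr$ipae_max + runif(1, 0.02, 0.4),
           ddg = thr$ddg_max + runif(1, 2, 40),
           sap = thr$sap_max + runif(1, 1, 30),
           cms = thr$cms_min - runif(1, 20, min(250, thr$cms_min)),
           rmsd_pred = thr$rmsd_pred_max + runif(1, 0.2, 3))
  }

  rows <- vector("list", n)
  passes <- c(rep(TRUE, planted_pass_count),
              rep(FALSE, n - planted_pass_count))
  for (i in seq_len(n)) {
    vals <- setNames(vapply(metrics, sample_pass, numeric(1)), metrics)
    if (!passes[i]) {
      viol <- sample(metrics, sample(seq_along(metrics), 1))
      for (m in viol) vals[m] <- sample_fail(m)
    }
    row <- data.frame(
      design_id = sprintf("d%04d", i), target = preset$name,
      length = sample(12:18, 1),
      sequence = paste(sample(names(.aa1to3), 12, replace = TRUE),
                       collapse = ""),
      plddt = runif(1, 0.82, 0.98),
      ipae = NA_real_, rmsd_pred = runif(1, 0.2, 1.4),
      ddg = NA_real_, sap = NA_real_, cms = NA_real_,
      cluster = NA_integer_, stringsAsFactors = FALSE
    )
    for (m in metrics) row[[m]] <- vals[[m]]
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  tab <- tab[sample(n), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path)) write_metrics(tab, path)
  tab
}
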