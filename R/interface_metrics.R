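# Numerical solvent-accessible surface area and the coordinate-derived
# developability/interface metrics built on it. All SASA values are
# heavy-atom (hydrogens ignored), probe 1.4 A by default.

# Deterministic quasi-uniform unit-sphere point set (golden-spiral
# lattice); fixed by n_points, no RNG involved.
.sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  cbind(r * cos(phi), r * sin(phi), z)
}

# Deterministic canonical orientation: centroid at the origin, axes
# along the principal axes of the coordinate covariance, each axis sign
# fixed by the (rotation-invariant) third moment of the projections.
# Rigid motions of the input then leave the evaluated coordinates
# unchanged up to numerical precision, so the fixed point lattice gives
# rigid-motion-invariant areas.
.canonical_frame <- function(xyz) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(xyz) < 3) return(xyz)
  V <- eigen(crossprod(xyz), symmetric = TRUE)$vectors
  proj <- xyz %*% V
  for (k in 1:3) {
    if (sum(proj[, k]^3) < 0) proj[, k] <- -proj[, k]
  }
  proj
}

.atom_radii <- function(atoms, radii = NULL) {
  if (!is.null(atoms$radius)) return(atoms$radius)
  tab <- .vdw_radii
  if (!is.null(radii)) tab[names(radii)] <- radii
  el <- toupper(atoms$element)
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "),
         " (supply a `radius` column or a `radii` override)")
  unname(tab[el])
}

#' Shrake-Rupley numerical solvent-accessible surface area
#'
#' Per-atom SASA from a deterministic spherical point lattice: a surface
#' point at radius `r + probe` is exposed when it lies outside every
#' neighbouring atom's probe-expanded sphere; the atom area is the
#' exposed fraction times `4 pi (r + probe)^2`.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`
#'   (optionally `radius` to override the element lookup, and
#'   `chain`/`resno` for per-residue sums).
#' @param probe Probe radius in Angstrom.
#' @param n_points Number of lattice points per atom.
#' @param radii Optional named vector overriding element radii.
#' @return A `sasa_result`: list with `atom_area` (Angstrom^2 per atom),
#'   `residue_area` (named per chain:resno when available) and `total`.
#' @examples
#' a <- data.frame(element = "C", x = 0, y = 0, z = 0)
#' shrake_rupley(a)$total  # ~ 4*pi*(1.7+1.4)^2
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960, radii = NULL) {
  atoms <- as.data.frame(atoms)
  n <- nrow(atoms)
  if (n < 1) stop("need at least one atom")
  r <- .atom_radii(atoms, radii)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  # evaluate in a canonical molecular frame so the fixed point lattice
  # gives rigid-motion-invariant areas
  xyz <- .canonical_frame(xyz)
  pts <- .sphere_points(n_points)
  rp <- r + probe
  # candidate neighbours: occlusion possible only within r_i + r_j + 2 probe
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    cut <- (rp[i] + rp)^2
    nb <- which(d2[i, ] < cut)
    nb <- nb[nb != i]
    p <- sweep(pts * rp[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        exposed <- exposed & (dj2 >= rp[j]^2)
        if (!any(exposed)) break
      }
      frac <- mean(exposed)
    } else frac <- 1
    area[i] <- frac * 4 * pi * rp[i]^2
  }
  reskey <- if (!is.null(atoms$resno)) {
    ch <- if (is.null(atoms$chain)) "" else atoms$chain
    paste0(ch, ":", atoms$resno)
  } else NULL
  residue_area <- if (!is.null(reskey))
    tapply(area, reskey, sum) else NULL
  structure(
    list(atom_area = area, residue_area = residue_area,
         total = sum(area), probe = probe, n_points = n_points),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.1f A^2 (probe %.2f, %d points)\n",
              length(x$atom_area), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Buried interface area (contact molecular surface proxy)
#'
#' `(SASA(binder alone) + SASA(target alone) - SASA(complex)) / 2`, the
#' buried-SASA proxy for the contact-molecular-surface (CMS) metric.
#' Side-chain atoms are used when present. Note this is a proxy: values
#' are comparable within this package, but absolute comparability with
#' surface areas from other interface calculators is not guaranteed.
#'
#' @param complex A `complex_structure` with at least one target chain.
#' @inheritParams shrake_rupley
#' @return Buried interface area in Angstrom^2.
#' @export
contact_surface <- function(complex, probe = 1.4, n_points = 960,
                            radii = NULL) {
  stopifnot(inherits(complex, "complex_structure"))
  at <- complex$atoms
  bnd <- at[at$role == "binder", , drop = FALSE]
  tgt <- at[at$role == "target", , drop = FALSE]
  if (nrow(bnd) == 0L || nrow(tgt) == 0L)
    stop("contact_surface needs both binder and target atoms")
  s_b <- shrake_rupley(bnd, probe, n_points, radii)$total
  s_t <- shrake_rupley(tgt, probe, n_points, radii)$total
  s_c <- shrake_rupley(at, probe, n_points, radii)$total
  (s_b + s_t - s_c) / 2
}

#' Spatial aggregation propensity (SAP)
#'
#' Hydrophobicity-weighted, exposure-weighted surface patch score. For
#' atom `i`, SAP sums over residues `r` the residue hydrophobicity
#' (Black-Mould scale, zeroed at glycine) times the relative exposure of
#' the side-chain atoms of `r` lying within `R` of `i`: their SASA in
#' the full structure divided by the side-chain SASA of that residue
#' computed in isolation (the fully exposed reference). The design score
#' is the sum of positive per-atom values; high values flag
#' aggregation-prone hydrophobic patches.
#'
#' @param x A `complex_structure` (its binder atoms are scored) or an
#'   atom data frame with `chain`, `resno`, `resid`, `elety`, `element`,
#'   `x`, `y`, `z`, `is_side_chain`. Side-chain atoms must be present:
#'   backbone-only models cannot be scored.
#' @param R Patch radius in Angstrom.
#' @inheritParams shrake_rupley
#' @return A `sap_result`: list with `atom_sap` (per-atom values) and
#'   `score` (sum of positive values).
#' @export
sap_score <- function(x, R = 5, probe = 1.4, n_points = 960) {
  atoms <- if (inherits(x, "complex_structure"))
    x$atoms[x$atoms$role == "binder", , drop = FALSE]
  else as.data.frame(x)
  need <- c("resno", "resid", "elety", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atom table must carry columns: ", paste(need, collapse = ", "))
  if (is.null(atoms$is_side_chain))
    atoms$is_side_chain <- !(atoms$elety %in% .backbone_atom_names)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  reskey <- paste0(atoms$chain, ":", atoms$resno)
  bad <- unique(reskey[!(atoms$resid %in% c(names(.bm_hydrophobicity)))])
  if (length(bad))
    stop("no hydrophobicity reference for residue(s): ",
         paste(bad, collapse = ", "))
  no_sc <- tapply(atoms$is_side_chain, reskey, sum) == 0
  non_gly <- tapply(atoms$resid != "GLY", reskey, any)
  if (any(no_sc & non_gly))
    stop("side-chain atoms are required for SAP; supply full-atom ",
         "models (backbone-only residue(s): ",
         paste(names(no_sc)[no_sc & non_gly], collapse = ", "), ")")

  sasa <- shrake_rupley(atoms, probe, n_points)$atom_area
  # fully exposed reference: side-chain SASA of each residue in isolation
  ref <- vapply(unique(reskey), function(k) {
    sel <- reskey == k
    if (!any(atoms$is_side_chain[sel])) return(NA_real_)
    iso <- shrake_rupley(atoms[sel, , drop = FALSE], probe, n_points)
    sum(iso$atom_area[atoms$is_side_chain[sel]])
  }, numeric(1))

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(atoms)
  sap <- numeric(n)
  sc_idx <- which(atoms$is_side_chain)
  for (i in seq_len(n)) {
    near_sc <- sc_idx[d[i, sc_idx] <= R]
    if (!length(near_sc)) next
    by_res <- split(near_sc, reskey[near_sc])
    for (k in names(by_res)) {
      hyd <- .bm_hydrophobicity[[atoms$resid[by_res[[k]][1]]]]
      sap[i] <- sap[i] + hyd * sum(sasa[by_res[[k]]]) / ref[[k]]
    }
  }
  structure(
    list(atom_sap = sap, score = sum(sap[sap > 0]),
         residue_ref_sasa = ref),
    class = "sap_result"
  )
}

#' @export
print.sap_result <- function(x, ...) {
  cat(sprintf("sap_result: design score %.2f over %d atoms\n",
              x$score, length(x$atom_sap)))
  invisible(x)
}

.parse_hotspots <- function(hotspots) {
  if (is.data.frame(hotspots)) return(hotspots[, c("chain", "resno")])
  parts <- strsplit(as.character(hotspots), ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Hotspot contact coverage of a binder-target interface
#'
#' A hotspot residue is contacted when any of its heavy atoms lies
#' within `cutoff` of any binder heavy atom; coverage is the contacted
#' fraction of the supplied hotspot list. Also reports all binder-target
#' residue pairs in contact with their minimum heavy-atom distance.
#'
#' @param complex A `complex_structure`.
#' @param hotspots Character vector `"chain:resno"` (e.g. `"B:46"`) or a
#'   data frame with `chain` and `resno` columns.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return An `interface_report`: list with `hotspot_coverage`,
#'   `contacted` (logical per hotspot), `contacts` (data frame of binder
#'   residue, target chain/residue, min distance) and `n_contacts`.
#' @export
hotspot_contacts <- function(complex, hotspots, cutoff = 5.0) {
  stopifnot(inherits(complex, "complex_structure"))
  hs <- .parse_hotspots(hotspots)
  at <- complex$atoms
  bnd <- at[at$role == "binder", , drop = FALSE]
  tgt <- at[at$role == "target", , drop = FALSE]
  if (nrow(tgt) == 0L) stop("complex has no target atoms")
  tkey <- paste0(tgt$chain, ":", tgt$resno)
  hkey <- paste0(hs$chain, ":", hs$resno)
  missing <- setdiff(hkey, tkey)
  if (length(missing))
    stop("unknown hotspot residue(s): ", paste(missing, collapse = ", "))

  bx <- as.matrix(bnd[, c("x", "y", "z")])
  tx <- as.matrix(tgt[, c("x", "y", "z")])
  # min heavy-atom distance per (binder residue, target residue) pair
  d <- sqrt(outer(rowSums(bx^2), rep(1, nrow(tx))) +
              outer(rep(1, nrow(bx)), rowSums(tx^2)) - 2 * bx %*% t(tx))
  bres <- bnd$resno
  pair_min <- tapply(as.vector(d),
                     list(binder = rep(bres, times = nrow(tgt)),
                          target = rep(tkey, each = nrow(bnd))), min)
  res_min <- apply(pair_min, 2, min, na.rm = TRUE)
  contacted <- res_min[hkey] <= cutoff
  names(contacted) <- hkey

  idx <- which(pair_min <= cutoff, arr.ind = TRUE)
  contacts <- if (nrow(idx)) {
    data.frame(binder_resno = as.integer(rownames(pair_min)[idx[, 1]]),
               target = colnames(pair_min)[idx[, 2]],
               min_distance = pair_min[idx],
               stringsAsFactors = FALSE)
  } else data.frame(binder_resno = integer(0), target = character(0),
                    min_distance = numeric(0))
  structure(
    list(hotspot_coverage = mean(contacted), contacted = contacted,
         contacts = contacts, n_contacts = nrow(contacts),
         cutoff = cutoff),
    class = "interface_report"
  )
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: coverage %.2f (%d/%d hotspots), %d contact residues (cutoff %.1f A)\n",
              x$hotspot_coverage, sum(x$contacted), length(x$contacted),
              x$n_contacts, x$cutoff))
  invisible(x)
}
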