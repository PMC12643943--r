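#' Macrocycle backbone structure
#'
#' Ordered backbone residues (atoms N, CA, C required; O optional) with a
#' cyclic flag and a one-letter sequence. Coordinates are stored as an
#' `L x 4 x 3` array with atom dimension `c("N","CA","C","O")`; a missing
#' O is `NA`.
#'
#' @param coords `L x 4 x 3` numeric array (atom dim named N, CA, C, O),
#'   or `L x 3 x 3` (N, CA, C only).
#' @param sequence One-letter sequence string or character vector of
#'   length `L`; defaults to poly-glycine.
#' @param cyclic Logical; is the chain head-to-tail cyclized?
#' @return A `macrocycle_structure` object.
#' @export
macrocycle_structure <- function(coords, sequence = NULL, cyclic = TRUE) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  L <- dim(coords)[1]
  atoms <- dimnames(coords)[[2]]
  if (is.null(atoms)) atoms <- c("N", "CA", "C", "O")[seq_len(dim(coords)[2])]
  full <- array(NA_real_, c(L, 4, 3),
                dimnames = list(NULL, c("N", "CA", "C", "O"),
                                c("x", "y", "z")))
  full[, atoms, ] <- coords
  if (cyclic && L < 3) stop("a cyclic structure needs at least 3 residues")
  req <- full[, c("N", "CA", "C"), , drop = FALSE]
  if (anyNA(req)) stop("atoms N, CA and C are required for every residue")
  if (!all(is.finite(req))) stop("coordinates must be finite")
  if (is.null(sequence)) sequence <- rep("G", L)
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) != L)
    stop("sequence length must equal residue count")
  structure(
    list(coords = full, sequence = as.character(sequence),
         cyclic = isTRUE(cyclic)),
    class = "macrocycle_structure"
  )
}

#' @export
print.macrocycle_structure <- function(x, ...) {
  cat(sprintf("macrocycle_structure: %d residues, %s\n",
              n_residues(x), if (x$cyclic) "cyclic" else "linear"))
  cat(" sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Number of residues of a structure
#' @param x A `macrocycle_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(x) dim(x$coords)[1]

#' Extract the C-alpha coordinate matrix
#' @param x A `macrocycle_structure`.
#' @return `L x 3` numeric matrix.
#' @export
ca_coords <- function(x) {
  m <- x$coords[, "CA", , drop = FALSE]
  dim(m) <- c(dim(x$coords)[1], 3)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Rotate the residue numbering of a closed macrocycle
#'
#' Relabels the ring so that old residue `k + 1` becomes residue 1. On a
#' closed ring the starting point is arbitrary; this helper creates the
#' register-shifted copies used to exercise the cyclic-register search of
#' [tm_score()].
#'
#' @param x A cyclic `macrocycle_structure`.
#' @param k Integer rotation (0 <= k < L).
#' @return The relabeled structure.
#' @export
rotate_indices <- function(x, k) {
  if (!isTRUE(x$cyclic)) stop("index rotation requires a cyclic structure")
  L <- n_residues(x)
  k <- as.integer(k) %% L
  idx <- ((seq_len(L) - 1L + k) %% L) + 1L
  macrocycle_structure(x$coords[idx, , , drop = FALSE],
                       sequence = x$sequence[idx], cyclic = TRUE)
}

.atom_element <- function(elety) {
  # First alphabetic character of the PDB atom name identifies the
  # element for standard protein heavy atoms (SE for MSE handled too).
  e <- toupper(sub("^[0-9']*", "", elety))
  ifelse(substr(e, 1, 2) == "SE", "SE", substr(e, 1, 1))
}

#' Read a backbone structure or complex from a PDB file
#'
#' Parses ATOM records (first model; altloc blank or 'A'; heteroatoms
#' skipped), orders residues by chain, residue number and insertion code,
#' and splits the system into a binder macrocycle plus target chains.
#' Binder residues must carry N, CA and C; a missing O is tolerated.
#' Target chains keep all heavy atoms (side chains included when
#' present).
#'
#' @param path PDB file path.
#' @param binder_chain Chain id of the macrocycle.
#' @param cyclic Logical; mark the binder as cyclized.
#' @return A `complex_structure`: list with `binder`
#'   ([macrocycle_structure()]), `binder_chain`, `targets` (character
#'   vector of target chain ids) and `atoms` (data frame of all heavy
#'   atoms with columns chain, resno, resid, elety, element, x, y, z,
#'   role, is_side_chain).
#' @export
read_backbone_pdb <- function(path, binder_chain = "A", cyclic = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$element <- .atom_element(at$elety)
  at <- at[at$element != "H", , drop = FALSE]
  ord <- order(at$chain, at$resno, at$insert)
  at <- at[ord, , drop = FALSE]
  if (!binder_chain %in% at$chain)
    stop("binder chain '", binder_chain, "' not present in ", path)

  bnd <- at[at$chain == binder_chain, , drop = FALSE]
  reskey <- paste(bnd$resno, bnd$insert)
  keys <- unique(reskey)
  L <- length(keys)
  coords <- array(NA_real_, c(L, 4, 3),
                  dimnames = list(NULL, c("N", "CA", "C", "O"),
                                  c("x", "y", "z")))
  seq1 <- character(L)
  for (r in seq_len(L)) {
    rows <- bnd[reskey == keys[r], , drop = FALSE]
    for (a in c("N", "CA", "C", "O")) {
      hit <- which(rows$elety == a)
      if (length(hit))
        coords[r, a, ] <- as.numeric(rows[hit[1], c("x", "y", "z")])
    }
    miss <- c("N", "CA", "C")[is.na(coords[r, c("N", "CA", "C"), 1])]
    if (length(miss))
      stop(sprintf("binder residue %s %s is missing backbone atom(s) %s",
                   rows$resid[1], keys[r], paste(miss, collapse = ",")))
    seq1[r] <- if (rows$resid[1] %in% names(.aa3to1))
      .aa3to1[[rows$resid[1]]] else "X"
  }
  binder <- macrocycle_structure(coords, sequence = seq1, cyclic = cyclic)

  atoms <- data.frame(
    chain = at$chain, resno = at$resno, insert = at$insert,
    resid = at$resid, elety = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z,
    role = ifelse(at$chain == binder_chain, "binder", "target"),
    is_side_chain = !(at$elety %in% .backbone_atom_names),
    stringsAsFactors = FALSE
  )
  structure(
    list(binder = binder, binder_chain = binder_chain,
         targets = setdiff(unique(atoms$chain), binder_chain),
         atoms = atoms),
    class = "complex_structure"
  )
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("complex_structure: binder chain %s (%d aa), %d target chain(s)\n",
              x$binder_chain, n_residues(x$binder), length(x$targets)))
  invisible(x)
}

#' Assemble a complex from a binder and target atoms
#'
#' Builds a `complex_structure` in code (no file round trip), e.g. for
#' synthetic fixtures. `target_atoms` uses the same columns as the
#' `atoms` slot of [read_backbone_pdb()] (chain, resno, resid, elety,
#' x, y, z; element/role/is_side_chain are derived when absent).
#'
#' @param binder A [macrocycle_structure()].
#' @param target_atoms Data frame of target heavy atoms.
#' @param binder_chain Chain id given to the binder.
#' @param binder_atoms Optional data frame of full-atom binder records
#'   (side chains); backbone atoms are always derived from `binder`.
#' @return A `complex_structure`.
#' @export
make_complex <- function(binder, target_atoms = NULL, binder_chain = "A",
                         binder_atoms = NULL) {
  stopifnot(inherits(binder, "macrocycle_structure"))
  bb <- .binder_backbone_atoms(binder, binder_chain)
  extra <- list(bb)
  if (!is.null(binder_atoms)) {
    binder_atoms <- .complete_atom_df(binder_atoms, role = "binder")
    extra <- c(extra, list(binder_atoms))
  }
  if (!is.null(target_atoms)) {
    target_atoms <- .complete_atom_df(target_atoms, role = "target")
    extra <- c(extra, list(target_atoms))
  }
  atoms <- do.call(rbind, extra)
  structure(
    list(binder = binder, binder_chain = binder_chain,
         targets = setdiff(unique(atoms$chain[atoms$role == "target"]),
                           binder_chain),
         atoms = atoms),
    class = "complex_structure"
  )
}

.complete_atom_df <- function(df, role) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$insert)) df$insert <- ""
  if (is.null(df$resid)) df$resid <- "GLY"
  if (is.null(df$element)) df$element <- .atom_element(df$elety)
  df$role <- role
  df$is_side_chain <- !(df$elety %in% .backbone_atom_names)
  df[, c("chain", "resno", "insert", "resid", "elety", "element",
         "x", "y", "z", "role", "is_side_chain")]
}

.binder_backbone_atoms <- function(binder, chain) {
  L <- n_residues(binder)
  rows <- list()
  for (r in seq_len(L)) {
    for (a in c("N", "CA", "C", "O")) {
      xyz <- binder$coords[r, a, ]
      if (anyNA(xyz)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = r, insert = "",
        resid = if (binder$sequence[r] %in% names(.aa1to3))
          .aa1to3[[binder$sequence[r]]] else "GLY",
        elety = a, element = substr(a, 1, 1),
        x = xyz[1], y = xyz[2], z = xyz[3],
        role = "binder", is_side_chain = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Write a backbone structure or complex to a PDB file
#'
#' Emits ATOM records for all stored atoms (backbone atoms for a
#' macrocycle; every heavy atom of a complex), preserving chain ids.
#'
#' @param x A `macrocycle_structure` or `complex_structure`.
#' @param path Output file path.
#' @param chain Chain id used when writing a bare macrocycle.
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(x, path, chain = "A") {
  if (inherits(x, "macrocycle_structure")) {
    at <- .binder_backbone_atoms(x, chain)
  } else if (inherits(x, "complex_structure")) {
    at <- x$atoms
  } else stop("unsupported type for write_backbone_pdb")
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", nrow(at)),
    resno = at$resno, resid = at$resid, chain = at$chain,
    insert = ifelse(at$insert == "", NA, at$insert),
    elety = at$elety, eleno = seq_len(nrow(at))
  )
  invisible(path)
}

#' Per-residue backbone torsion set
#'
#' Holds phi/psi/omega in degrees on (-180, 180]; `NA` marks torsions
#' undefined at the termini of a linear chain. For a cyclic structure the
#' wraparound makes all `L` torsions defined.
#'
#' @param phi,psi,omega Numeric vectors of equal length (degrees).
#' @param cyclic Logical flag carried for provenance.
#' @return A `torsion_set` (data frame with attribute `cyclic`).
#' @export
torsion_set <- function(phi, psi, omega = rep(180, length(phi)),
                        cyclic = TRUE) {
  n <- length(phi)
  stopifnot(length(psi) == n, length(omega) == n)
  chk <- function(v, nm) {
    bad <- !is.na(v) & (v <= -180 | v > 180)
    if (any(bad)) stop(nm, " torsions must lie in (-180, 180]")
  }
  chk(phi, "phi"); chk(psi, "psi"); chk(omega, "omega")
  out <- data.frame(phi = phi, psi = psi, omega = omega)
  attr(out, "cyclic") <- isTRUE(cyclic)
  class(out) <- c("torsion_set", "data.frame")
  out
}

#' Build an open backbone from torsions with ideal geometry
#'
#' Places backbone atoms N, CA, C (and carbonyl O) by natural chain
#' extension with the ideal bond lengths and angles of
#' [backbone_geometry()]. The chain is left open: `phi[1]`, `psi[L]` and
#' `omega[L]` do not affect the open backbone (ring closure is handled by
#' [ccd_close()]), but `psi[L]` seeds the closing virtual frame when
#' present.
#'
#' @param torsions A [torsion_set()] (or data frame with phi/psi/omega
#'   columns in degrees).
#' @param sequence Optional sequence (defaults to poly-glycine).
#' @return An open (non-cyclic) [macrocycle_structure()].
#' @export
build_from_torsions <- function(torsions, sequence = NULL) {
  tor <- as.data.frame(torsions)
  L <- nrow(tor)
  if (L < 3) stop("need at least 3 residues")
  for (nm in c("phi", "psi", "omega")) {
    v <- tor[[nm]]
    if (any(!is.na(v) & (v <= -180 | v > 180)))
      stop(nm, " torsions must lie in (-180, 180]")
  }
  g <- .bb_geom
  co <- array(NA_real_, c(L, 4, 3),
              dimnames = list(NULL, c("N", "CA", "C", "O"),
                              c("x", "y", "z")))
  # Residue 1 in a canonical frame.
  co[1, "N", ] <- c(0, 0, 0)
  co[1, "CA", ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * .deg2rad
  co[1, "C", ] <- co[1, "CA", ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (r in seq_len(L - 1)) {
    psi <- tor$psi[r]; omg <- tor$omega[r]; phi <- tor$phi[r + 1]
    if (anyNA(c(psi, omg, phi)))
      stop("psi[1..L-1], omega[1..L-1] and phi[2..L] must be defined")
    co[r + 1, "N", ] <- place_atom(co[r, "N", ], co[r, "CA", ], co[r, "C", ],
                                   g$b_c_n, g$a_ca_c_n, psi)
    co[r + 1, "CA", ] <- place_atom(co[r, "CA", ], co[r, "C", ],
                                    co[r + 1, "N", ],
                                    g$b_n_ca, g$a_c_n_ca, omg)
    co[r + 1, "C", ] <- place_atom(co[r, "C", ], co[r + 1, "N", ],
                                   co[r + 1, "CA", ],
                                   g$b_ca_c, g$a_n_ca_c, phi)
    co[r, "O", ] <- place_atom(co[r, "N", ], co[r, "CA", ], co[r, "C", ],
                               g$b_c_o, g$a_ca_c_o, wrap_angle(psi + 180))
  }
  psiL <- tor$psi[L]
  co[L, "O", ] <- place_atom(co[L, "N", ], co[L, "CA", ], co[L, "C", ],
                             g$b_c_o, g$a_ca_c_o,
                             wrap_angle((if (is.na(psiL)) 0 else psiL) + 180))
  out <- macrocycle_structure(co, sequence = sequence, cyclic = FALSE)
  attr(out, "seed_psi_L") <- psiL
  out
}

#' Measure backbone torsions
#'
#' Standard phi/psi/omega dihedrals in degrees. For a cyclic structure
#' the definitions wrap: `phi[1]` uses `C` of residue `L`, `psi[L]` uses
#' `N` of residue 1 and `omega[L]` is the dihedral across the closing
#' bond, so all `L` (phi, psi) pairs are defined. For a linear structure
#' `phi[1]`, `psi[L]` and `omega[L]` are `NA`.
#'
#' @param structure A [macrocycle_structure()].
#' @return A [torsion_set()].
#' @export
measure_torsions <- function(structure) {
  stopifnot(inherits(structure, "macrocycle_structure"))
  co <- structure$coords
  L <- dim(co)[1]
  P <- function(r, a) co[((r - 1) %% L) + 1, a, ]
  phi <- psi <- omg <- rep(NA_real_, L)
  for (r in seq_len(L)) {
    if (r > 1 || structure$cyclic)
      phi[r] <- dihedral(P(r - 1, "C"), P(r, "N"), P(r, "CA"), P(r, "C"))
    if (r < L || structure$cyclic)
      psi[r] <- dihedral(P(r, "N"), P(r, "CA"), P(r, "C"), P(r + 1, "N"))
    if (r < L || structure$cyclic)
      omg[r] <- dihedral(P(r, "CA"), P(r, "C"), P(r + 1, "N"), P(r + 1, "CA"))
  }
  torsion_set(phi, psi, omg, cyclic = structure$cyclic)
}

#' Validate the N-to-C ring closure of a macrocycle
#'
#' Measures the closing peptide bond `C(L)-N(1)`: bond length, the two
#' flanking bond angles (CA-C-N and C-N-CA) and the omega dihedral across
#' the bond, and compares them with ideal peptide geometry.
#'
#' @param structure A cyclic [macrocycle_structure()].
#' @param tol_len Bond-length tolerance (Angstrom) about the ideal
#'   1.329.
#' @param tol_ang Bond-angle tolerance (degrees) about the ideal values.
#' @param tol_omega Tolerance (degrees) of `|omega|` about 180 (trans).
#' @param allow_cis Also accept omega near 0 (cis closing bond).
#' @return A `closure_report`: bond_length, angle deviations,
#'   omega, and `pass`.
#' @export
closure_check <- function(structure, tol_len = 0.2, tol_ang = 15,
                          tol_omega = 30, allow_cis = FALSE) {
  stopifnot(inherits(structure, "macrocycle_structure"))
  if (!isTRUE(structure$cyclic))
    stop("closure_check requires a cyclic structure")
  g <- .bb_geom
  co <- structure$coords
  L <- dim(co)[1]
  cl <- co[L, "C", ]; n1 <- co[1, "N", ]
  blen <- .vnorm(cl - n1)
  a1 <- bond_angle(co[L, "CA", ], cl, n1)          # CA-C-N
  a2 <- bond_angle(cl, n1, co[1, "CA", ])          # C-N-CA
  omg <- dihedral(co[L, "CA", ], cl, n1, co[1, "CA", ])
  dev1 <- a1 - g$a_ca_c_n
  dev2 <- a2 - g$a_c_n_ca
  omega_dev <- min(abs(abs(omg) - 180),
                   if (allow_cis) abs(omg) else Inf)
  pass <- abs(blen - g$b_c_n) <= tol_len &&
    abs(dev1) <= tol_ang && abs(dev2) <= tol_ang &&
    omega_dev <= tol_omega
  structure(
    list(bond_length = blen, angle_dev_ca_c_n = dev1,
         angle_dev_c_n_ca = dev2, omega = omg, pass = pass,
         tolerances = list(tol_len = tol_len, tol_ang = tol_ang,
                           tol_omega = tol_omega, allow_cis = allow_cis)),
    class = "closure_report"
  )
}

#' @export
print.closure_report <- function(x, ...) {
  cat(sprintf(
    "closure_report: bond %.3f A, angle dev %.1f/%.1f deg, omega %.1f deg -> %s\n",
    x$bond_length, x$angle_dev_ca_c_n, x$angle_dev_c_n_ca, x$omega,
    if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Ramachandran histogram of a torsion set
#'
#' 2D histogram of the defined (phi, psi) pairs on half-open bins
#' `[lo, hi)` covering `[-180, 180)` in both dimensions.
#'
#' @param torsions A [torsion_set()] (or data frame with phi/psi).
#' @param bin_width Bin width in degrees; must divide 360.
#' @return Integer matrix of counts (rows phi, columns psi) with bin
#'   lower bounds as dimnames; counts sum to the number of defined
#'   pairs.
#' @export
ramachandran_counts <- function(torsions, bin_width = 10) {
  if (360 %% bin_width != 0) stop("`bin_width` must divide 360")
  tor <- as.data.frame(torsions)
  nb <- as.integer(360 / bin_width)
  lo <- seq(-180, 180 - bin_width, by = bin_width)
  h <- matrix(0L, nb, nb, dimnames = list(phi = lo, psi = lo))
  ok <- !is.na(tor$phi) & !is.na(tor$psi)
  if (!any(ok)) return(h)
  # the half-open convention puts +180 into the top bin's closed edge;
  # fold it to -180 so every angle lands in [lo, hi)
  fold <- function(x) ifelse(x == 180, -180, x)
  bi <- findInterval(fold(tor$phi[ok]), lo)
  bj <- findInterval(fold(tor$psi[ok]), lo)
  for (k in seq_along(bi)) h[bi[k], bj[k]] <- h[bi[k], bj[k]] + 1L
  h
}
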