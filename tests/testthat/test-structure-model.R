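test_that("building from torsions and measuring them round-trips at interior residues", {
  for (tor in list(helical_torsions(12),
                   torsion_set(rep(-120, 8), rep(120, 8), rep(180, 8)))) {
    L <- nrow(tor)
    s <- build_from_torsions(tor)
    m <- measure_torsions(s)
    expect_lt(max(abs(m$phi[2:L] - tor$phi[2:L])), 1e-6)
    expect_lt(max(abs(m$psi[1:(L - 1)] - tor$psi[1:(L - 1)])), 1e-6)
    expect_lt(max(abs(abs(m$omega[1:(L - 1)]) - 180)), 1e-6)
    expect_true(is.na(m$phi[1]) && is.na(m$psi[L]))
  }
})

test_that("extended chains stretch further than helical ones at equal length", {
  ee <- function(tor) {
    ca <- ca_coords(build_from_torsions(tor))
    sqrt(sum((ca[1, ] - ca[nrow(ca), ])^2))
  }
  expect_gt(ee(torsion_set(rep(-120, 8), rep(120, 8), rep(180, 8))),
            ee(helical_torsions(8)))
})

test_that("a minimal 3-residue build emits all required backbone atoms", {
  s <- build_from_torsions(helical_torsions(3))
  expect_equal(sum(!is.na(s$coords[, c("N", "CA", "C"), 1])), 9)
  expect_error(build_from_torsions(helical_torsions(2)), "3 residues")
  expect_error(torsion_set(181, 0, 180), "phi")
})

test_that("cyclic torsion measurement wraps across the closing bond", {
  mc <- closed_fixture(10)
  tor <- measure_torsions(mc)
  expect_equal(sum(!is.na(tor$phi) & !is.na(tor$psi)), 10)
  lin <- mc; lin$cyclic <- FALSE
  tl <- measure_torsions(lin)
  expect_equal(sum(!is.na(tl$phi)), 9)
  expect_equal(sum(!is.na(tl$psi)), 9)
})

test_that("closure validation accepts CCD-closed rings and rejects broken ones", {
  mc <- closed_fixture(12)
  expect_true(closure_check(mc)$pass)

  open_helix <- build_from_torsions(helical_torsions(12))
  open_helix$cyclic <- TRUE
  rep_open <- closure_check(open_helix)
  expect_false(rep_open$pass)
  expect_gt(rep_open$bond_length, 10)

  shifted <- mc
  shifted$coords[1, , ] <- shifted$coords[1, , ] + 5
  expect_false(closure_check(shifted)$pass)

  lin <- mc; lin$cyclic <- FALSE
  expect_error(closure_check(lin), "cyclic")
})

test_that("torsions, closure measures and histograms are rigid-motion invariant", {
  mc <- closed_fixture(12, seed = 3)
  R <- random_rotation_fix(7)
  moved <- rigid_transform(mc, R, c(11.5, -4.2, 8.9))
  t0 <- measure_torsions(mc); t1 <- measure_torsions(moved)
  expect_lt(max(abs(t0$phi - t1$phi)), 1e-9)
  expect_lt(max(abs(t0$psi - t1$psi)), 1e-9)
  c0 <- closure_check(mc); c1 <- closure_check(moved)
  expect_lt(abs(c0$bond_length - c1$bond_length), 1e-9)
  expect_lt(abs(c0$omega - c1$omega), 1e-9)
  expect_identical(ramachandran_counts(t0), ramachandran_counts(t1))
})

test_that("rotating the residue order of a closed ring rotates its torsion list", {
  mc <- closed_fixture(11, seed = 5)
  k <- 4
  rot <- rotate_indices(mc, k)
  t0 <- measure_torsions(mc); t1 <- measure_torsions(rot)
  idx <- ((seq_len(11) - 1 + k) %% 11) + 1
  expect_equal(t1$phi, t0$phi[idx], tolerance = 1e-9)
  expect_equal(t1$psi, t0$psi[idx], tolerance = 1e-9)
})

test_that("PDB write/read round-trips coordinates to format precision", {
  mc <- closed_fixture(12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(mc, f, chain = "A")
  back <- read_backbone_pdb(f, binder_chain = "A", cyclic = TRUE)
  expect_equal(n_residues(back$binder), 12)
  expect_lt(max(abs(ca_coords(back$binder) - ca_coords(mc))), 1e-3 + 1e-12)
  expect_lt(max(abs(back$binder$coords - mc$coords), na.rm = TRUE),
            1e-3 + 1e-12)
})

test_that("PDB parsing separates binder and target chains and enforces backbone completeness", {
  cx <- synthetic_complex(L = 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(cx, f)
  back <- read_backbone_pdb(f, binder_chain = "A")
  expect_equal(n_residues(back$binder), 12)
  expect_equal(back$targets, "B")
  expect_equal(sum(back$atoms$role == "target"), 30 * 4)
  expect_error(read_backbone_pdb(f, binder_chain = "Q"), "binder chain")

  # CA-only binder residues are an error that names the residue
  lines <- readLines(f)
  drop <- grepl("^ATOM", lines) &
    substr(lines, 22, 22) == "A" &
    trimws(substr(lines, 23, 26)) == "3" &
    trimws(substr(lines, 13, 16)) != "CA"
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[!drop], f2)
  expect_error(read_backbone_pdb(f2, binder_chain = "A"), "residue.*3|3.*missing")
})

test_that("first altloc wins when a PDB carries alternates", {
  mc <- closed_fixture(8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(mc, f)
  lines <- readLines(f)
  iatom <- which(grepl("^ATOM", lines) &
                   trimws(substr(lines, 13, 16)) == "CA" &
                   trimws(substr(lines, 23, 26)) == "2")[1]
  la <- lines[iatom]
  substr(la, 17, 17) <- "A"
  lb <- lines[iatom]
  substr(lb, 17, 17) <- "B"
  # shift the B-altloc x by ~ +9 A
  substr(lb, 31, 38) <- sprintf("%8.3f",
                                as.numeric(substr(lb, 31, 38)) + 9)
  lines <- append(lines[-iatom], c(la, lb), after = iatom - 1)
  writeLines(lines, f)
  back <- read_backbone_pdb(f, binder_chain = "A")
  expect_lt(abs(ca_coords(back$binder)[2, 1] - ca_coords(mc)[2, 1]), 1e-3)
})

test_that("ramachandran histograms respect bins, mass and degenerate input", {
  tor <- torsion_set(rep(-57, 100), rep(-47, 100))
  h <- ramachandran_counts(tor, 10)
  expect_equal(sum(h), 100)
  expect_equal(max(h), 100)
  expect_equal(unname(h["-60", "-50"]), 100)

  empty <- ramachandran_counts(torsion_set(numeric(0), numeric(0)), 10)
  expect_equal(sum(empty), 0)
  expect_error(ramachandran_counts(tor, 7), "divide")

  # planted basin mixture is recovered within sampling error
  cfg <- generator_config(length = 20, basin_weights = c(0.7, 0.3, 0),
                          jitter = 8, seed = 21, n = 40)
  set.seed(cfg$seed)
  frac <- mean(replicate(40, {
    t1 <- cyclopep:::.sample_torsions_impl(cfg)
    mean(attr(t1, "basin") == "helical")
  }))
  h2 <- ramachandran_counts(
    torsion_set(rnorm(2000, -57, 8), rnorm(2000, -47, 8)), 10)
  helical_mass <- sum(h2[as.character(seq(-90, -30, 10)),
                         as.character(seq(-80, -20, 10))])
  expect_gt(helical_mass / sum(h2), 0.95)
  expect_equal(frac, 0.7, tolerance = 0.05 / 0.7)
})
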