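test_that("kabsch recovers exact rigid motions and strips translations", {
  set.seed(2)
  X <- matrix(rnorm(24), 8, 3)
  R <- random_rotation_fix(3)
  Y <- sweep(X %*% R, 2, c(4, -2, 7), `+`)
  f <- kabsch(X, Y)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(apply_superposition(f, Y) - X)), 1e-8)

  f2 <- kabsch(X, sweep(X, 2, c(1, 0, 0), `+`))
  expect_lt(f2$rmsd, 1e-9)

  expect_error(kabsch(X[1:2, ], X[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch attains the Monte-Carlo rotation-search optimum", {
  set.seed(10)
  for (rep in 1:6) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(3 * n), n, 3)
    Y <- matrix(rnorm(3 * n), n, 3)
    ana <- kabsch(X, Y)$rmsd
    mc <- min(mc_min_rmsd(X, Y, n_rot = 100000, seed = rep))
    expect_lte(ana, mc + 1e-9)
    expect_lt(mc - ana, 1e-3)
  }
})

test_that("TM-score is exact on identity, recovers register shifts and dips below 0.5 for distinct shapes", {
  mc <- closed_fixture(16, seed = 5)
  self <- tm_score(mc, mc)
  expect_equal(self$score, 1.0, tolerance = 1e-9)
  expect_identical(self$register_shift, 0L)

  for (k in c(3L, 9L)) {
    r <- tm_score(mc, rotate_indices(mc, k))
    expect_equal(r$score, 1.0, tolerance = 1e-9)
    expect_identical(r$register_shift, k)
  }

  noisy <- perturb(mc, 3.0, seed = 8)
  expect_lt(tm_score(mc, noisy)$score, 0.5)

  expect_error(tm_score(ca_coords(mc), ca_coords(mc)[1:10, ]), "equal length")
})

test_that("TM-score is rigid-motion invariant and decreases with noise amplitude", {
  mc <- closed_fixture(14, seed = 9)
  moved <- rigid_transform(mc, random_rotation_fix(4), c(3, 3, -12))
  p <- perturb(mc, 0.4, seed = 2)
  expect_equal(tm_score(mc, p)$score,
               tm_score(moved, rigid_transform(p, random_rotation_fix(4),
                                               c(3, 3, -12)))$score,
               tolerance = 1e-6)
  mean_tm <- function(amp) {
    mean(vapply(1:6, function(s)
      tm_score(mc, perturb(mc, amp, seed = s))$score, numeric(1)))
  }
  scores <- vapply(c(0.2, 0.8, 2.0), mean_tm, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_true(all(scores > 0 & scores <= 1))
})

test_that("pairwise TM matrices are symmetric with unit diagonal and separate distinct fixtures", {
  mc <- closed_fixture(12, seed = 2)
  twin <- rotate_indices(mc, 5)
  distinct <- perturb(mc, 3.0, seed = 4)
  M <- pairwise_tm_matrix(list(a = mc, b = twin, c = distinct))
  expect_identical(M, t(M))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_equal(M["a", "b"], 1.0, tolerance = 1e-9)
  expect_lt(M["a", "c"], 0.5)
  expect_lt(M["b", "c"], 0.5)
  expect_equal(dim(pairwise_tm_matrix(list())), c(0L, 0L))
})

test_that("greedy clustering follows the most-neighbours rule with deterministic ties", {
  # 3 identical + 1 distinct -> clusters of sizes {3, 1}
  M <- matrix(0.2, 4, 4); diag(M) <- 1
  M[1:3, 1:3] <- 0.9
  cl <- greedy_cluster(M, 0.5)
  expect_equal(cl$n_clusters, 2)
  expect_equal(sort(table(cl$labels), decreasing = TRUE),
               sort(table(c(1, 1, 1, 2)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_identical(cl$representatives[1], 1L)  # tie -> lowest index

  none <- matrix(0.1, 5, 5); diag(none) <- 1
  expect_equal(greedy_cluster(none, 0.5)$n_clusters, 5)
  all_m <- matrix(0.9, 5, 5)
  expect_equal(greedy_cluster(all_m, 0.5)$n_clusters, 1)
  expect_error(greedy_cluster(matrix(0, 2, 3)), "square")

  # members always reach their representative at the threshold
  set.seed(6)
  S <- matrix(runif(100), 10, 10); S <- (S + t(S)) / 2; diag(S) <- 1
  for (thr in c(0.3, 0.5, 0.7)) {
    cla <- greedy_cluster(S, thr)
    reps <- cla$representatives[cla$labels]
    ok <- vapply(seq_len(10), function(i)
      i == reps[i] || S[i, reps[i]] >= thr, logical(1))
    expect_true(all(ok))
  }
  # raising the threshold never decreases the cluster count
  counts <- vapply(seq(0.1, 0.9, 0.1),
                   function(t) greedy_cluster(S, t)$n_clusters, numeric(1))
  expect_true(all(diff(counts) >= 0))
  # identical inputs give identical assignments
  expect_identical(greedy_cluster(S, 0.5), greedy_cluster(S, 0.5))
})

test_that("the two r.m.s.d. conventions behave as constructed", {
  cx <- synthetic_complex(L = 12, seed = 11)
  expect_equal(ca_rmsd_target_aligned(cx, cx), 0, tolerance = 1e-9)
  expect_equal(ca_rmsd_macrocycle_aligned(cx$binder, cx$binder), 0,
               tolerance = 1e-9)

  # binder displaced 2 A with the target fixed
  disp <- cx
  disp$binder <- rigid_transform(disp$binder, diag(3), c(0, 2, 0))
  expect_equal(ca_rmsd_target_aligned(disp, cx), 2, tolerance = 1e-6)

  # seeded 0.5 A noise: macrocycle-aligned value within the expected band
  noisy <- perturb(cx$binder, 0.5, seed = 20)
  v <- ca_rmsd_macrocycle_aligned(noisy, cx$binder)
  expect_gt(v, 0.3); expect_lt(v, 1.2)
  expect_equal(v, kabsch(ca_coords(cx$binder), ca_coords(noisy))$rmsd,
               tolerance = 1e-12)

  # target-aligned >= macrocycle-aligned for the same pair
  noisy_cx <- cx; noisy_cx$binder <- noisy
  expect_gte(ca_rmsd_target_aligned(noisy_cx, cx) + 1e-12,
             ca_rmsd_macrocycle_aligned(noisy, cx$binder))

  # both conventions are rigid-motion invariant
  R <- random_rotation_fix(12)
  moved <- rigid_transform(noisy_cx, R, c(5, 6, 7))
  expect_equal(ca_rmsd_target_aligned(moved, cx),
               ca_rmsd_target_aligned(noisy_cx, cx), tolerance = 1e-6)
  expect_equal(ca_rmsd_macrocycle_aligned(rigid_transform(noisy, R, c(1, 2, 3)),
                                          cx$binder),
               ca_rmsd_macrocycle_aligned(noisy, cx$binder),
               tolerance = 1e-6)
})

test_that("multiple reference binder copies report the closest copy", {
  cx <- synthetic_complex(L = 10, seed = 3)
  # reference carries a second, perturbed binder copy as an extra chain
  copy2 <- perturb(cx$binder, 1.5, seed = 31)
  extra <- do.call(rbind, lapply(seq_len(n_residues(copy2)), function(r) {
    data.frame(chain = "C", resno = r, resid = "GLY", elety = "CA",
               x = ca_coords(copy2)[r, 1], y = ca_coords(copy2)[r, 2],
               z = ca_coords(copy2)[r, 3], stringsAsFactors = FALSE)
  }))
  ref <- make_complex(cx$binder, rbind(
    cyclopep:::.complete_atom_df(synthetic_target_atoms(), "target"),
    cyclopep:::.complete_atom_df(extra, "target")))
  got <- ca_rmsd_target_aligned(cx, ref, ref_binder_chains = c("A", "C"))
  expect_equal(got, 0, tolerance = 1e-9)
})
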