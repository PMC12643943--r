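#' Length-dependent TM-score distance scale d0
#'
#' `d0 = max(d0_min, 1.24 * (L - 15)^(1/3) - 1.8)`. For the short chain
#' lengths of macrocycles the cube-root formula is negative or
#' undefined, so a floor `d0_min` (default 0.5 Angstrom, common practice
#' for short chains) applies.
#'
#' @param L Chain length used for normalization.
#' @param d0_min Floor in Angstrom.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L, d0_min = 0.5) {
  x <- L - 15
  raw <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  max(d0_min, raw)
}

.as_ca_matrix <- function(x) {
  if (inherits(x, "macrocycle_structure")) return(ca_coords(x))
  if (is.matrix(x) && ncol(x) == 3) return(x)
  stop("expected a macrocycle_structure or an n x 3 coordinate matrix")
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rigid superposition of point set `Y` onto `X`
#' (closed-form via singular value decomposition; reflections are
#' rejected). The fit satisfies `Yfit = Y %*% rotation + translation`.
#'
#' @param X,Y `n x 3` coordinate matrices in correspondence, `n >= 3`.
#' @return List with `rotation` (3 x 3, det +1), `translation`
#'   (length 3) and `rmsd` (Angstrom over the fitted atoms).
#' @export
kabsch <- function(X, Y) {
  X <- .as_ca_matrix(X); Y <- .as_ca_matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point sets must have equal size")
  if (nrow(X) < 3) stop("need at least 3 points")
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate (collinear) point set")
  fit <- .cpp_kabsch(X, Y)
  fit$translation <- as.vector(fit$translation)
  fit
}

#' Apply a Kabsch fit to coordinates
#' @param fit Result of [kabsch()].
#' @param Y `n x 3` matrix to transform.
#' @return Transformed matrix.
#' @export
apply_superposition <- function(fit, Y) {
  sweep(Y %*% fit$rotation, 2, -fit$translation)
}

#' TM-score of two equal-length macrocycle backbones
#'
#' `TM = max over correspondences of (1/L) * sum_i 1 / (1 + (d_i/d0)^2)`
#' with `d0 = max(d0_min, 1.24 (L-15)^(1/3) - 1.8)`, each correspondence
#' scored by iterative fragment-seeded superposition refinement. With
#' `allow_cyclic_shift` all `L` register shifts of the ring (and, when
#' `allow_reversal`, the reversed residue order) are searched and the
#' best correspondence kept. Structures are compared at fixed index
#' correspondence (equal lengths; no structural alignment).
#'
#' @param A,B [macrocycle_structure()]s or `L x 3` C-alpha matrices of
#'   equal length `L >= 3`.
#' @param allow_cyclic_shift Search all cyclic register shifts.
#' @param allow_reversal Also search the reversed residue order.
#' @param d0_min Floor of the d0 scale (Angstrom).
#' @return List with `score` in (0, 1], `d0`, `register_shift` (the
#'   shift `s` pairing A residue `(i + s) mod L` with B residue `i`) and
#'   `reversed`.
#' @export
tm_score <- function(A, B, allow_cyclic_shift = TRUE,
                     allow_reversal = FALSE, d0_min = 0.5) {
  A <- .as_ca_matrix(A); B <- .as_ca_matrix(B)
  if (nrow(A) != nrow(B)) stop("structures must have equal length")
  if (nrow(A) < 3) stop("need at least 3 residues")
  d0 <- tm_d0(nrow(A), d0_min)
  r <- .cpp_tm_score(A, B, d0, allow_cyclic_shift, allow_reversal)
  list(score = r$score, d0 = d0, register_shift = r$register_shift,
       reversed = r$reversed)
}

#' All-by-all TM-score matrix
#'
#' Symmetric matrix of pairwise TM-scores over a set of equal-length
#' structures (diagonal 1; the fixed-correspondence score of equal-length
#' chains is direction-symmetric by construction).
#'
#' @param structures List of [macrocycle_structure()]s or `L x 3`
#'   matrices, all the same length.
#' @inheritParams tm_score
#' @return `n x n` symmetric numeric matrix (named after the list names
#'   when present).
#' @export
pairwise_tm_matrix <- function(structures, allow_cyclic_shift = TRUE,
                               allow_reversal = FALSE, d0_min = 0.5) {
  n <- length(structures)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  cs <- lapply(structures, .as_ca_matrix)
  Ls <- vapply(cs, nrow, integer(1))
  if (length(unique(Ls)) != 1L)
    stop("all structures must have equal length")
  M <- .cpp_pairwise_tm(cs, tm_d0(Ls[1], d0_min),
                        allow_cyclic_shift, allow_reversal)
  dimnames(M) <- list(names(structures), names(structures))
  M
}

#' Greedy threshold clustering of a similarity matrix
#'
#' Iteratively picks the unassigned structure with the most unassigned
#' neighbours at similarity >= `threshold` (ties broken by lowest input
#' index) as a cluster representative and assigns it together with those
#' neighbours; repeats until every structure is assigned. Used for
#' uniqueness/diversity counting of designed backbones at TM-score 0.5.
#'
#' @param matrix Square symmetric similarity matrix (e.g. from
#'   [pairwise_tm_matrix()]).
#' @param threshold Similarity threshold (default 0.5).
#' @return A `cluster_assignment`: list with integer `labels` (cluster
#'   id per structure), `representatives` (structure index per cluster)
#'   and `n_clusters`.
#' @export
greedy_cluster <- function(matrix, threshold = 0.5) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("`matrix` must be square")
  n <- nrow(matrix)
  labels <- rep(NA_integer_, n)
  reps <- integer(0)
  adj <- matrix >= threshold
  diag(adj) <- FALSE
  cl <- 0L
  while (anyNA(labels)) {
    un <- which(is.na(labels))
    deg <- vapply(un, function(i) sum(adj[i, un]), numeric(1))
    rep_i <- un[which.max(deg)]      # which.max takes the first maximum
    cl <- cl + 1L
    members <- un[adj[rep_i, un]]
    labels[c(rep_i, members)] <- cl
    reps <- c(reps, rep_i)
  }
  structure(
    list(labels = labels, representatives = reps, n_clusters = cl,
         threshold = threshold, ids = rownames(matrix)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d structures in %d clusters (threshold %.2f)\n",
              length(x$labels), x$n_clusters, x$threshold))
  invisible(x)
}

.target_ca_table <- function(cx, exclude_chains = character(0)) {
  at <- cx$atoms
  at <- at[at$role == "target" & at$elety == "CA" &
             !(at$chain %in% exclude_chains), , drop = FALSE]
  at
}

#' Target-aligned C-alpha r.m.s.d. of the macrocycle
#'
#' The design-versus-experiment convention in which model and reference
#' complexes are superposed on their shared target C-alpha atoms
#' (matched by chain and residue number) and the unfitted C-alpha
#' r.m.s.d. is then reported over the binder. When the reference holds
#' several binder copies (e.g. multiple copies in the asymmetric unit),
#' the minimum over copies is reported.
#'
#' @param model,reference `complex_structure`s with a shared target
#'   residue numbering (>= 3 shared target C-alpha atoms).
#' @param ref_binder_chains Chain ids in `reference` holding binder
#'   copies; defaults to the reference's own binder chain. Extra copies
#'   listed here are excluded from the target fit.
#' @return C-alpha r.m.s.d. in Angstrom.
#' @export
ca_rmsd_target_aligned <- function(model, reference,
                                   ref_binder_chains = reference$binder_chain) {
  stopifnot(inherits(model, "complex_structure"),
            inherits(reference, "complex_structure"))
  mt <- .target_ca_table(model)
  rt <- .target_ca_table(reference, exclude_chains = ref_binder_chains)
  key <- function(d) paste(d$chain, d$resno, d$insert)
  shared <- intersect(key(mt), key(rt))
  if (length(shared) < 3)
    stop("fewer than 3 shared target C-alpha atoms")
  mt <- mt[match(shared, key(mt)), ]
  rt <- rt[match(shared, key(rt)), ]
  fit <- kabsch(as.matrix(rt[, c("x", "y", "z")]),
                as.matrix(mt[, c("x", "y", "z")]))
  model_ca <- apply_superposition(fit, ca_coords(model$binder))

  copies <- list()
  ref_cas <- reference$atoms[reference$atoms$elety == "CA", , drop = FALSE]
  for (ch in unique(c(reference$binder_chain, ref_binder_chains))) {
    if (ch == reference$binder_chain) {
      copies[[ch]] <- ca_coords(reference$binder)
    } else {
      sel <- ref_cas[ref_cas$chain == ch, , drop = FALSE]
      if (nrow(sel)) copies[[ch]] <- as.matrix(sel[, c("x", "y", "z")])
    }
  }
  vals <- vapply(copies, function(cc) {
    if (nrow(cc) != nrow(model_ca)) return(NA_real_)
    sqrt(mean(rowSums((model_ca - cc)^2)))
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no reference binder copy matches the model binder length")
  min(vals)
}

#' Macrocycle-aligned C-alpha r.m.s.d.
#'
#' Kabsch fit on the binder C-alpha atoms only, r.m.s.d. over the same
#' atoms: the "aligned by macrocycle alone" convention.
#'
#' @param model,reference [macrocycle_structure()]s (or complexes, whose
#'   binders are used) of equal length.
#' @return C-alpha r.m.s.d. in Angstrom.
#' @export
ca_rmsd_macrocycle_aligned <- function(model, reference) {
  pick <- function(x) if (inherits(x, "complex_structure")) x$binder else x
  A <- .as_ca_matrix(pick(model))
  B <- .as_ca_matrix(pick(reference))
  if (nrow(A) != nrow(B)) stop("binder lengths differ")
  kabsch(A, B)$rmsd
}
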