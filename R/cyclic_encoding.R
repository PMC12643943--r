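#' Signed cyclic relative-position offset
#'
#' Relative position of residue `j` with respect to residue `i` on a
#' head-to-tail cyclized chain of length `L`. Offsets are counted along
#' the ring, switching from positive (rightward) to negative (leftward)
#' once `j` lies more than halfway around the ring from `i`, so the last
#' and first residues are nearest neighbours (`offset = -1`), as required
#' when the termini are joined by a peptide bond.
#'
#' At even `L` the antipode (`j` exactly halfway around) is ambiguous;
#' the positive branch `+L/2` is returned so the map is single-valued.
#'
#' @param i,j Integer vectors of 0-based residue indices (recycled).
#' @param L Chain length (single positive integer).
#' @return Integer vector of signed offsets with `|offset| <= floor(L/2)`.
#' @examples
#' cyclic_offset(0, 9, 10)   # -1: termini are adjacent on the ring
#' cyclic_offset(2, 9, 12)   # -5: shortest signed path is leftward
#' @export
cyclic_offset <- function(i, j, L) {
  if (length(L) != 1L || !is.finite(L) || L < 1 || L != round(L))
    stop("`L` must be a single positive integer")
  i <- as.integer(i); j <- as.integer(j)
  if (anyNA(i) || anyNA(j)) stop("indices must be non-missing integers")
  if (any(i < 0L | i >= L) || any(j < 0L | j >= L))
    stop("indices must satisfy 0 <= i, j < L")
  L <- as.integer(L)
  d <- (j - i) %% L
  ifelse(d > L / 2, d - L, d)
}

#' Chain layout for a relative-position encoding
#'
#' Describes the chains of a (possibly multichain) system: each chain has
#' an id, a length and a kind, `"cyclic"` (macrocycle, offsets wrap) or
#' `"linear"` (target chain, standard offsets).
#'
#' @param chain_id Character vector of unique chain identifiers.
#' @param length Integer vector of chain lengths (>= 1).
#' @param kind Character vector, each `"cyclic"` or `"linear"`.
#' @return A `chain_layout` object.
#' @examples
#' chain_layout(c("A", "B"), c(12, 150), c("cyclic", "linear"))
#' @export
chain_layout <- function(chain_id, length, kind) {
  chain_id <- as.character(chain_id)
  length <- as.integer(length)
  kind <- match.arg(as.character(kind), c("cyclic", "linear"),
                    several.ok = TRUE)
  n <- base::length(chain_id)
  if (n == 0L) stop("layout must contain at least one chain")
  if (base::length(length) != n || base::length(kind) != n)
    stop("`chain_id`, `length` and `kind` must have equal lengths")
  if (anyDuplicated(chain_id)) stop("chain ids must be unique")
  if (any(is.na(length)) || any(length < 1L))
    stop("chain lengths must be >= 1")
  structure(
    list(chain_id = chain_id, length = length, kind = kind),
    class = "chain_layout"
  )
}

#' @export
print.chain_layout <- function(x, ...) {
  cat("chain_layout:", sum(x$length), "residues\n")
  for (k in seq_along(x$chain_id))
    cat(sprintf("  %s  L=%d  %s\n", x$chain_id[k], x$length[k], x$kind[k]))
  invisible(x)
}

#' Relative-position offset matrix for a chain layout
#'
#' Builds the square signed-offset matrix over all residues of a layout.
#' Within a cyclic chain, offsets wrap via [cyclic_offset()]; within a
#' linear chain the standard offset `j - i` is used; interchain entries
#' are set to `sentinel` and flagged in the mask (the mask, not the
#' sentinel value, is authoritative).
#'
#' @param layout A [chain_layout()].
#' @param sentinel Integer stored at interchain entries. The default is
#'   far outside any plausible clamp bound.
#' @return A `relpos_matrix` object: list with integer matrix `offsets`,
#'   logical matrix `mask` (TRUE at interchain entries), `sentinel`, and
#'   the generating `layout`.
#' @examples
#' rp <- relpos_matrix(chain_layout("A", 3, "cyclic"))
#' rp$offsets[1, ]  # 0 1 -1
#' @export
relpos_matrix <- function(layout, sentinel = -1000000L) {
  if (!inherits(layout, "chain_layout")) stop("`layout` must be a chain_layout")
  n <- sum(layout$length)
  chain_of <- rep(seq_along(layout$chain_id), layout$length)
  pos <- unlist(lapply(layout$length, function(L) seq_len(L) - 1L))
  off <- matrix(as.integer(sentinel), n, n)
  mask <- outer(chain_of, chain_of, `!=`)
  for (k in seq_along(layout$chain_id)) {
    idx <- which(chain_of == k)
    L <- layout$length[k]
    ii <- matrix(pos[idx], L, L)
    jj <- t(ii)
    blk <- if (layout$kind[k] == "cyclic") {
      matrix(cyclic_offset(as.vector(ii), as.vector(jj), L), L, L)
    } else {
      jj - ii
    }
    off[idx, idx] <- as.integer(blk)
  }
  structure(
    list(offsets = off, mask = mask, sentinel = as.integer(sentinel),
         layout = layout),
    class = "relpos_matrix"
  )
}

#' @export
print.relpos_matrix <- function(x, ...) {
  cat(sprintf("relpos_matrix: %d x %d (%d masked interchain entries)\n",
              nrow(x$offsets), ncol(x$offsets), sum(x$mask)))
  invisible(x)
}

#' Clamp relative-position offsets to a bound
#'
#' Replaces every non-masked entry by `min(max(entry, -bmax), +bmax)`, the
#' binning bound used by downstream encoders. Masked (interchain) entries
#' are left unchanged.
#'
#' @param matrix A [relpos_matrix()].
#' @param bmax Positive integer clamp bound.
#' @return A clamped `relpos_matrix`.
#' @export
clamp_offsets <- function(matrix, bmax) {
  if (!inherits(matrix, "relpos_matrix")) stop("`matrix` must be a relpos_matrix")
  if (length(bmax) != 1L || !is.finite(bmax) || bmax < 1 || bmax != round(bmax))
    stop("`bmax` must be a single integer >= 1")
  bmax <- as.integer(bmax)
  off <- matrix$offsets
  keep <- !matrix$mask
  off[keep] <- pmin(pmax(off[keep], -bmax), bmax)
  matrix$offsets <- off
  matrix
}

#' Write a relative-position matrix as TSV
#'
#' Emits a tab-separated integer matrix with `NA` at masked (interchain)
#' cells.
#'
#' @param matrix A [relpos_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_relpos_tsv <- function(matrix, path) {
  off <- matrix$offsets
  off[matrix$mask] <- NA_integer_
  utils::write.table(off, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
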