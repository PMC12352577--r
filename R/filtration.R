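#' Flag (clique) complex filtration of a dissimilarity matrix
#'
#' Enumerates every clique of size `<= max_dim + 1` and assigns it the
#' filtration value `max` of its pairwise dissimilarities (0 for vertices):
#' the Vietoris-Rips rule, equivalent to inserting a simplex as soon as all
#' its edges are present in the threshold graph. Simplices are returned in a
#' valid filtration order -- sorted by (value, dimension, lexicographic
#' vertex tuple) -- so faces always precede cofaces.
#'
#' To measure homology in dimension `p`, simplices up to dimension `p + 1`
#' must be enumerated, hence `max_dim = 3` (the default) for H2.
#'
#' @param D a [dissimilarity_matrix()] (an [fc_matrix()] is converted).
#' @param max_dim highest simplex dimension retained, in `1:3`.
#' @param n_cap guard on the region count when `max_dim = 3` (the complex
#'   has `choose(n, 4)` tetrahedra).
#' @return object of class `filtered_complex` with flat fields `verts`
#'   (1-based vertex indices, concatenated), `offsets` (0-based), `filt`,
#'   `dim`, plus `n`, `max_dim`, `region_ids`.
#' @export
build_flag_filtration <- function(D, max_dim = 3, n_cap = 80) {
  if (inherits(D, "fc_matrix")) D <- dissimilarity_matrix(D)
  if (!(max_dim %in% 1:3)) stop("max_dim must be 1, 2 or 3")
  Dm <- unclass(D)
  n <- nrow(Dm)
  if (max_dim == 3 && n > n_cap) {
    stop("n = ", n, " exceeds the cap (", n_cap, ") for max_dim = 3; ",
         "lower max_dim or raise n_cap")
  }
  V <- list()
  filt <- list()
  dims <- list()
  # vertices
  V[[1]] <- matrix(seq_len(n), ncol = 1)
  filt[[1]] <- rep(0, n)
  dims[[1]] <- rep(0L, n)
  if (n >= 2) {
    pairs <- t(combn(n, 2))
    V[[2]] <- pairs
    filt[[2]] <- Dm[pairs]
    dims[[2]] <- rep(1L, nrow(pairs))
  }
  pair_d <- function(S, i, j) Dm[S[, c(i, j), drop = FALSE]]
  if (max_dim >= 2 && n >= 3) {
    tri <- t(combn(n, 3))
    filt[[3]] <- pmax(pair_d(tri, 1, 2), pair_d(tri, 1, 3), pair_d(tri, 2, 3))
    V[[3]] <- tri
    dims[[3]] <- rep(2L, nrow(tri))
  }
  if (max_dim >= 3 && n >= 4) {
    qd <- t(combn(n, 4))
    filt[[4]] <- pmax(pair_d(qd, 1, 2), pair_d(qd, 1, 3), pair_d(qd, 1, 4),
                      pair_d(qd, 2, 3), pair_d(qd, 2, 4), pair_d(qd, 3, 4))
    V[[4]] <- qd
    dims[[4]] <- rep(3L, nrow(qd))
  }
  m <- sum(vapply(V, nrow, 0L))
  Vm <- matrix(NA_integer_, m, 4)
  r0 <- 0
  for (b in seq_along(V)) {
    nb <- nrow(V[[b]])
    Vm[r0 + seq_len(nb), seq_len(ncol(V[[b]]))] <- V[[b]]
    r0 <- r0 + nb
  }
  fv <- unlist(filt, use.names = FALSE)
  dv <- unlist(dims, use.names = FALSE)
  ord <- order(fv, dv, Vm[, 1], Vm[, 2], Vm[, 3], Vm[, 4])
  Vm <- Vm[ord, , drop = FALSE]
  fv <- fv[ord]
  dv <- dv[ord]
  flat <- as.vector(t(Vm))
  flat <- flat[!is.na(flat)]
  structure(list(verts = as.integer(flat),
                 offsets = as.integer(c(0L, cumsum(dv + 1L))),
                 filt = fv, dim = dv, n = n, max_dim = as.integer(max_dim),
                 region_ids = rownames(Dm) %||% paste0("R", seq_len(n))),
            class = "filtered_complex")
}

#' @export
print.filtered_complex <- function(x, ...) {
  cat("<filtered_complex> ", x$n, " vertices, ", length(x$filt),
      " simplices up to dim ", x$max_dim, "\n", sep = "")
  invisible(x)
}

#' Persistence diagrams of a filtered flag complex
#'
#' Standard boundary-matrix reduction over the two-element field. Each
#' (positive, negative) simplex pair yields an interval (birth, death);
#' unpaired positive simplices yield essential classes, whose death is
#' capped at 1.0, the endpoint of the filtration domain (at `d = 1` every
#' edge is present, so the single surviving component is the only essential
#' class when weights are positive). Diagrams are reported for dimensions
#' `0 .. max_dim - 1`; the top enumerated dimension is dropped because its
#' deaths are not resolved. Zero-persistence intervals (birth = death) are
#' recorded -- distance computations exclude them by default.
#'
#' @param fc_complex a [build_flag_filtration()] result.
#' @return data frame of class `persistence_diagrams` with columns
#'   `dimension`, `birth`, `death`, `essential` and attribute `n_vertices`.
#' @export
compute_persistence <- function(fc_complex) {
  if (!inherits(fc_complex, "filtered_complex")) {
    stop("fc_complex must be a filtered_complex")
  }
  res <- .cpp_reduce_persistence(fc_complex$verts, fc_complex$offsets,
                                 fc_complex$filt)
  df <- data.frame(dimension = as.integer(res[, 1]),
                   birth = res[, 2], death = res[, 3],
                   essential = res[, 4] == 1)
  df <- df[df$dimension < fc_complex$max_dim, , drop = FALSE]
  df$death[df$essential] <- 1.0
  df <- df[order(df$dimension, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_vertices = fc_complex$n, max_dim = fc_complex$max_dim,
            class = c("persistence_diagrams", "data.frame"))
}

#' Extract the intervals of one homological dimension
#'
#' @param dgms a `persistence_diagrams` data frame.
#' @param p homological dimension.
#' @return data frame of intervals (possibly zero rows).
#' @export
diagram <- function(dgms, p) {
  out <- dgms[dgms$dimension == p, c("birth", "death", "essential"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Betti curves from persistence diagrams
#'
#' `betti_p(t)` counts the intervals alive at `t`: finite intervals with
#' `birth <= t < death` plus essential classes with `birth <= t`.
#'
#' @param dgms a `persistence_diagrams` data frame.
#' @param thresholds sorted ascending filtration values.
#' @param dims dimensions to evaluate (default: all present in `dgms`).
#' @return data frame of class `betti_curve` with columns `threshold`,
#'   `dimension`, `betti`.
#' @export
betti_curve <- function(dgms, thresholds, dims = NULL) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  dims <- dims %||% sort(unique(dgms$dimension))
  out <- do.call(rbind, lapply(dims, function(p) {
    d <- dgms[dgms$dimension == p, , drop = FALSE]
    b <- vapply(thresholds, function(t) {
      sum(d$birth <= t & (d$essential | t < d$death))
    }, 0)
    data.frame(threshold = thresholds, dimension = p, betti = as.integer(b))
  }))
  rownames(out) <- NULL
  structure(out, class = c("betti_curve", "data.frame"))
}

# ---- brute-force validation oracle ------------------------------------------

# rank of a 0/1 matrix over GF(2), rows bit-packed into 31-bit words
.gf2_rank <- function(M) {
  nr <- nrow(M)
  nc <- ncol(M)
  if (nr == 0 || nc == 0) return(0L)
  nw <- (nc + 30L) %/% 31L
  bits <- matrix(0L, nr, nw)
  for (w in seq_len(nw)) {
    cols <- (((w - 1L) * 31L) + 1L):min(w * 31L, nc)
    pw <- 2^(seq_along(cols) - 1)
    bits[, w] <- as.integer(M[, cols, drop = FALSE] %*% pw)
  }
  active <- rep(TRUE, nr)
  rank <- 0L
  for (j in seq_len(nc)) {
    w <- (j - 1L) %/% 31L + 1L
    mask <- bitwShiftL(1L, (j - 1L) %% 31L)
    rows <- which(active & bitwAnd(bits[, w], mask) != 0L)
    if (length(rows) == 0) next
    piv <- rows[1]
    rest <- rows[-1]
    if (length(rest)) {
      bits[rest, ] <- bitwXor(bits[rest, , drop = FALSE],
                              matrix(bits[piv, ], length(rest), nw, byrow = TRUE))
    }
    active[piv] <- FALSE
    rank <- rank + 1L
  }
  rank
}

# cliques of `size` vertices in adjacency matrix A (logical, diag FALSE),
# as a matrix with one sorted clique per row
.cliques_of_size <- function(A, size) {
  n <- nrow(A)
  if (size == 1) return(matrix(seq_len(n), ncol = 1))
  if (n < size) return(matrix(integer(0), ncol = size))
  cand <- t(combn(n, size))
  pairs <- combn(size, 2)
  ok <- rep(TRUE, nrow(cand))
  for (j in seq_len(ncol(pairs))) {
    ok <- ok & A[cand[, pairs[, j], drop = FALSE]]
  }
  cand[ok, , drop = FALSE]
}

# GF(2) boundary matrix from dim-(k-1) simplices (rows) to dim-k simplices
# (columns); simplices given as sorted-row matrices
.boundary_matrix <- function(faces, simplices) {
  nf <- nrow(faces)
  ns <- nrow(simplices)
  if (ns == 0 || nf == 0) return(matrix(0L, nf, ns))
  key <- function(m) apply(m, 1, paste, collapse = "-")
  fidx <- structure(seq_len(nf), names = key(faces))
  B <- matrix(0L, nf, ns)
  sz <- ncol(simplices)
  for (drop in seq_len(sz)) {
    fk <- key(simplices[, -drop, drop = FALSE])
    B[cbind(fidx[fk], seq_len(ns))] <- 1L
  }
  B
}

#' Brute-force Betti number at a fixed threshold
#'
#' Independent validation oracle: builds the full flag complex of the
#' threshold graph at `t` (edge iff `d_uv <= t`) and computes
#' `b_p = dim C_p - rank(boundary_p) - rank(boundary_{p+1})` by GF(2)
#' Gaussian elimination, with no shared code with the reduction-based
#' persistence path.
#'
#' @param D a [dissimilarity_matrix()].
#' @param t filtration threshold.
#' @param p homological dimension, in `0:2`.
#' @param n_guard combinatorial guard on the number of regions.
#' @return integer Betti number.
#' @export
brute_force_betti <- function(D, t, p, n_guard = 14) {
  if (inherits(D, "fc_matrix")) D <- dissimilarity_matrix(D)
  Dm <- unclass(D)
  n <- nrow(Dm)
  if (n > n_guard) stop("n = ", n, " exceeds the brute-force guard (", n_guard, ")")
  if (!(p %in% 0:2)) stop("p must be 0, 1 or 2")
  A <- Dm <= t
  diag(A) <- FALSE
  Cp <- .cliques_of_size(A, p + 1)
  if (nrow(Cp) == 0) return(0L)
  Cnext <- .cliques_of_size(A, p + 2)
  rank_next <- .gf2_rank(.boundary_matrix(Cp, Cnext))
  if (p == 0) {
    rank_p <- 0L
  } else {
    Cprev <- .cliques_of_size(A, p)
    rank_p <- .gf2_rank(.boundary_matrix(Cprev, Cp))
  }
  as.integer(nrow(Cp) - rank_p - rank_next)
}
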