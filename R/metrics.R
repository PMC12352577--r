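#' Distance of an interval to the diagonal
#'
#' For an interval `I = [x, y]` this is `(y - x) / 2`: the max-norm distance
#' of the point `(x, y)` to the diagonal of the persistence plane, the cost
#' of letting the class vanish (or appear) rather than matching it.
#'
#' @param birth,death interval endpoints (vectorized).
#' @return nonnegative numeric.
#' @export
interval_gap <- function(birth, death = NULL) {
  if (is.null(death)) {
    death <- birth[2]
    birth <- birth[1]
  }
  (death - birth) / 2
}

#' Max-norm distance between two intervals
#'
#' `d(I, J) = max(|x2 - x1|, |y2 - y1|)` for `I = [x1, y1]`, `J = [x2, y2]`.
#'
#' @param i,j length-2 numeric vectors `c(birth, death)`.
#' @return nonnegative numeric.
#' @export
interval_distance <- function(i, j) {
  max(abs(j[1] - i[1]), abs(j[2] - i[2]))
}

# Normalize diagram input to a 2-column (birth, death) matrix.
# Accepts: persistence_diagrams (single dimension required unless `dim`
# given), a data frame with birth/death columns, or a 2-column matrix.
.as_intervals <- function(x, dim = NULL, drop_zero = TRUE,
                          allow_essential = FALSE) {
  if (inherits(x, "persistence_diagrams") ||
      (is.data.frame(x) && all(c("birth", "death") %in% names(x)))) {
    if (!is.null(dim) && "dimension" %in% names(x)) {
      x <- x[x$dimension == dim, , drop = FALSE]
    } else if ("dimension" %in% names(x) && length(unique(x$dimension)) > 1) {
      stop("diagram spans several dimensions; pass dim= to select one")
    }
    if (!allow_essential && "essential" %in% names(x) && any(x$essential)) {
      stop("diagram contains essential intervals; these are excluded from ",
           "Wasserstein distances (use the H0 Hausdorff distance instead)")
    }
    m <- cbind(x$birth, x$death)
  } else if (is.matrix(x)) {
    if (ncol(x) != 2) stop("interval matrix must have 2 columns (birth, death)")
    m <- x
  } else if (is.null(x) || (is.numeric(x) && length(x) == 0)) {
    m <- matrix(numeric(0), ncol = 2)
  } else {
    stop("cannot interpret diagram input of class ", paste(class(x), collapse = "/"))
  }
  if (nrow(m) && any(m[, 2] < m[, 1])) stop("intervals must satisfy birth <= death")
  if (drop_zero && nrow(m)) m <- m[m[, 2] > m[, 1], , drop = FALSE]
  m
}

#' q-Wasserstein distance between persistence diagrams
#'
#' Exact minimal cost over all partial pairings: matched intervals pay their
#' max-norm distance, unmatched intervals on either side pay their distance
#' to the diagonal, every term raised to the power `q`, and the optimum
#' taken to the power `1/q`. Computed by solving a linear assignment problem
#' on the `(nX + nY)`-square cost matrix augmented with one
#' diagonal-projection slot per interval; diagonal-to-diagonal slots cost 0.
#'
#' Essential intervals are rejected: under the full-simplex filtration
#' endpoint H1/H2 have none, and H0 comparisons use
#' [hausdorff_h0_distance()]. Zero-persistence intervals are dropped by
#' default; they sit on the diagonal and contribute nothing.
#'
#' @param dgmX,dgmY diagrams: `persistence_diagrams`, a data frame with
#'   `birth`/`death` columns, or a 2-column matrix.
#' @param q order, must exceed 1 (default 2).
#' @param dim homological dimension to extract when a multi-dimension
#'   diagram object is passed.
#' @param drop_zero drop zero-persistence intervals first (default TRUE).
#' @return nonnegative numeric.
#' @export
wasserstein_distance <- function(dgmX, dgmY, q = 2, dim = NULL,
                                 drop_zero = TRUE) {
  if (!is.numeric(q) || length(q) != 1 || q <= 1) {
    stop("q must be a single number > 1")
  }
  X <- .as_intervals(dgmX, dim = dim, drop_zero = drop_zero)
  Y <- .as_intervals(dgmY, dim = dim, drop_zero = drop_zero)
  nx <- nrow(X)
  ny <- nrow(Y)
  if (nx == 0 && ny == 0) return(0)
  gx <- (X[, 2] - X[, 1]) / 2
  gy <- (Y[, 2] - Y[, 1]) / 2
  if (nx == 0) return(sum(gy^q)^(1 / q))
  if (ny == 0) return(sum(gx^q)^(1 / q))
  m <- nx + ny
  cost <- matrix(0, m, m)
  cost[seq_len(nx), seq_len(ny)] <-
    pmax(abs(outer(X[, 1], Y[, 1], "-")), abs(outer(X[, 2], Y[, 2], "-")))^q
  cost[seq_len(nx), ny + seq_len(nx)] <- matrix(gx^q, nx, nx)
  cost[nx + seq_len(ny), seq_len(ny)] <- matrix(gy^q, ny, ny, byrow = TRUE)
  sol <- .cpp_solve_lsap(cost)
  max(sol$cost, 0)^(1 / q)
}

# all permutations of 1..n as a list (tiny n only)
.perms <- function(n) {
  if (n == 0) return(list(integer(0)))
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .perms(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

#' Exhaustive-enumeration Wasserstein oracle
#'
#' Enumerates every partial pairing (subset choices times bijections) and
#' returns the minimum of the same objective as [wasserstein_distance()].
#' Exponential; guarded to at most 8 intervals total.
#'
#' @inheritParams wasserstein_distance
#' @return nonnegative numeric.
#' @export
brute_force_wasserstein <- function(dgmX, dgmY, q = 2, dim = NULL,
                                    drop_zero = TRUE) {
  if (q <= 1) stop("q must be > 1")
  X <- .as_intervals(dgmX, dim = dim, drop_zero = drop_zero)
  Y <- .as_intervals(dgmY, dim = dim, drop_zero = drop_zero)
  nx <- nrow(X)
  ny <- nrow(Y)
  if (nx + ny > 8) stop("size guard exceeded: |X| + |Y| = ", nx + ny, " > 8")
  gx <- (X[, 2] - X[, 1]) / 2
  gy <- (Y[, 2] - Y[, 1]) / 2
  best <- Inf
  for (s in 0:min(nx, ny)) {
    subX <- if (s == 0) list(integer(0)) else
      lapply(seq_len(ncol(combn(nx, s))), function(j) combn(nx, s)[, j])
    subY <- if (s == 0) list(integer(0)) else
      lapply(seq_len(ncol(combn(ny, s))), function(j) combn(ny, s)[, j])
    perms <- .perms(s)
    for (S0 in subX) for (T0 in subY) for (pp in perms) {
      matched <- 0
      if (s > 0) {
        for (t in seq_len(s)) {
          i <- S0[t]
          j <- T0[pp[t]]
          matched <- matched +
            max(abs(Y[j, 1] - X[i, 1]), abs(Y[j, 2] - X[i, 2]))^q
        }
      }
      unX <- setdiff(seq_len(nx), S0)
      unY <- setdiff(seq_len(ny), T0)
      tot <- (matched + sum(gx[unX]^q) + sum(gy[unY]^q))^(1 / q)
      if (tot < best) best <- tot
    }
  }
  if (nx == 0 && ny == 0) 0 else best
}

#' Hausdorff distance between H0 diagrams
#'
#' All H0 classes are born at 0, so the diagrams are fully described by
#' their death-value multisets (bars `[0, d]`); these are compared with the
#' classical Hausdorff distance on the real line:
#' `max( max_x min_y |d_x - d_y|, max_y min_x |d_x - d_y| )`.
#' The essential class (death capped at 1.0) is included -- both diagrams
#' then share the value 1.0 and it contributes 0. As a set distance it is
#' insensitive to multiplicity.
#'
#' @param dgmX,dgmY H0 diagrams (`persistence_diagrams` objects, data frames
#'   with a `death` column, or numeric death vectors).
#' @return nonnegative numeric.
#' @export
hausdorff_h0_distance <- function(dgmX, dgmY) {
  dx <- .h0_deaths(dgmX)
  dy <- .h0_deaths(dgmY)
  if (length(dx) == 0 || length(dy) == 0) stop("empty H0 diagram")
  directed <- function(a, b) max(vapply(a, function(v) min(abs(v - b)), 0))
  max(directed(dx, dy), directed(dy, dx))
}

.h0_deaths <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) return(x)
  if (is.data.frame(x)) {
    if ("dimension" %in% names(x)) x <- x[x$dimension == 0, , drop = FALSE]
    if (!"death" %in% names(x)) stop("no death column in H0 diagram input")
    return(x$death)
  }
  if (is.matrix(x) && ncol(x) == 2) return(x[, 2])
  stop("cannot interpret H0 diagram input")
}
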