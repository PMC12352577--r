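#' Construct a functional connectome matrix
#'
#' Validates and wraps a square symmetric weight matrix with entries in
#' \[0, 1\] and unit diagonal, the standard container for an absolute-valued
#' Pearson functional connectome. Slight numerical asymmetry (below `tol`)
#' is repaired by averaging with the transpose; anything larger is an error.
#'
#' @param W square numeric matrix of coupling weights.
#' @param region_ids character vector of region labels; defaults to the row
#'   names of `W` or `R1..Rn`.
#' @param tol numerical tolerance for the symmetry, range and diagonal checks.
#' @return a matrix of class `fc_matrix` with region ids as dimnames.
#' @export
fc_matrix <- function(W, region_ids = NULL, tol = 1e-8) {
  if (!is.matrix(W) || !is.numeric(W)) stop("W must be a numeric matrix")
  n <- nrow(W)
  if (n != ncol(W)) stop("W must be square")
  region_ids <- region_ids %||% rownames(W) %||% paste0("R", seq_len(n))
  if (length(region_ids) != n) stop("region_ids length must equal nrow(W)")
  if (anyDuplicated(region_ids)) stop("region_ids must be unique")
  asym <- max(abs(W - t(W)))
  if (asym > tol) stop("matrix is asymmetric beyond tolerance (max |W - t(W)| = ",
                       format(asym), ")")
  W <- (W + t(W)) / 2
  if (any(W < -tol) || any(W > 1 + tol)) stop("weights must lie in [0, 1]")
  W <- .clamp(W, 0, 1)
  if (max(abs(diag(W) - 1)) > tol) stop("diagonal must be exactly 1")
  diag(W) <- 1
  dimnames(W) <- list(region_ids, region_ids)
  structure(W, class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat("<fc_matrix> ", nrow(x), " regions, off-diagonal weights in [",
      format(min(x[upper.tri(x)]), digits = 3), ", ",
      format(max(x[upper.tri(x)]), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Functional connectome from regional time series
#'
#' Computes the absolute Pearson correlation between every pair of regional
#' signals. Rows are regions, columns are timepoints. The absolute value is
#' applied so that all couplings (and hence the threshold parameter) live in
#' \[0, 1\]; the diagonal is forced to exactly 1.
#'
#' @param ts numeric matrix, regions x timepoints.
#' @param region_ids optional region labels (defaults to rownames).
#' @return an [fc_matrix()].
#' @export
fc_from_timeseries <- function(ts, region_ids = NULL) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("ts must be a numeric matrix")
  if (ncol(ts) < 2) stop("need at least 2 timepoints per region")
  region_ids <- region_ids %||% rownames(ts) %||% paste0("R", seq_len(nrow(ts)))
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- region_ids[which(sds == 0)]
    stop("constant time series (undefined correlation) for region(s): ",
         paste(bad, collapse = ", "))
  }
  W <- abs(stats::cor(t(ts)))
  diag(W) <- 1
  fc_matrix(W, region_ids)
}

#' Entrywise group average of subject connectomes
#'
#' Subject matrices are already absolute-valued, so the mean is nonnegative
#' and remains a valid connectome.
#'
#' @param fcs non-empty list of [fc_matrix()] objects sharing region order.
#' @return an [fc_matrix()].
#' @export
group_average_fc <- function(fcs) {
  if (length(fcs) == 0) stop("empty list of connectomes")
  ids <- rownames(fcs[[1]])
  for (fc in fcs) {
    if (!identical(rownames(fc), ids)) stop("mismatched region_ids across subjects")
  }
  M <- Reduce(`+`, lapply(fcs, unclass)) / length(fcs)
  diag(M) <- 1
  fc_matrix(M, ids)
}

#' Dissimilarity matrix of a connectome
#'
#' The filtration parameter of all homological computations: `d = 1 - w`,
#' zero on the diagonal.
#'
#' @param fc an [fc_matrix()].
#' @return a matrix of class `dissimilarity_matrix`.
#' @export
dissimilarity_matrix <- function(fc) {
  D <- 1 - unclass(fc)
  diag(D) <- 0
  structure(D, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' Unique off-diagonal weight levels, decreasing
#'
#' The distinct coupling values of the connectome, i.e. the thresholds at
#' which the threshold graph actually changes. Uniqueness is exact
#' floating-point equality; pre-round the weights if coarser binning is
#' wanted.
#'
#' @param fc an [fc_matrix()].
#' @return numeric vector, strictly decreasing.
#' @export
weight_levels <- function(fc) {
  off <- unclass(fc)[upper.tri(fc)]
  sort(unique(off), decreasing = TRUE)
}

#' Threshold graph of a connectome
#'
#' Keeps the edge \{u, v\} iff `w_uv >= r` (ties included). Graphs are nested
#' across thresholds: raising `r` can only remove edges.
#'
#' @param fc an [fc_matrix()].
#' @param r threshold in \[0, 1\].
#' @return an object of class `threshold_graph` with fields `n`, `edges`
#'   (2-column index matrix), `r`, `region_ids`.
#' @export
threshold_graph <- function(fc, r) {
  if (!is.numeric(r) || length(r) != 1 || r < 0 || r > 1) {
    stop("threshold r must be a single value in [0, 1]")
  }
  W <- unclass(fc)
  A <- W >= r
  diag(A) <- FALSE
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  structure(list(n = nrow(W), edges = unname(idx), r = r,
                 region_ids = rownames(W)),
            class = "threshold_graph")
}

#' Graph-level Betti numbers
#'
#' `b0` is the number of connected components; `b1 = |E| - |V| + b0` is the
#' cycle rank (number of independent graph cycles). These are invariants of
#' the graph itself; once triangles of the clique complex fill in, the
#' complex-level `b1` (see [betti_curve()]) can be strictly smaller.
#'
#' @param g a [threshold_graph()].
#' @return named integer vector `c(b0 =, b1 =)`.
#' @export
graph_betti <- function(g) {
  n_edges <- nrow(g$edges)
  if (n_edges == 0) {
    b0 <- g$n
  } else {
    gr <- igraph::make_graph(t(g$edges), n = g$n, directed = FALSE)
    b0 <- igraph::components(gr)$no
  }
  c(b0 = as.integer(b0), b1 = as.integer(n_edges - g$n + b0))
}

#' Functional-network partition of the region set
#'
#' Assigns each region to exactly one of `k` non-empty classes by contiguous
#' blocks (the usual layout when regions are ordered by network).
#'
#' @param n_regions number of regions.
#' @param class_sizes integer sizes, summing to `n_regions`, all >= 1.
#' @param class_names optional class labels (default `FN1..FNk`).
#' @param region_ids optional region labels.
#' @return object of class `fn_partition`: list with `sigma` (integer
#'   membership vector named by region), `k`, `class_names`, `region_ids`.
#' @export
make_partition <- function(n_regions, class_sizes, class_names = NULL,
                           region_ids = NULL) {
  class_sizes <- as.integer(class_sizes)
  if (any(class_sizes < 1)) stop("every class must be non-empty")
  if (sum(class_sizes) != n_regions) {
    stop("class sizes sum to ", sum(class_sizes), ", expected ", n_regions)
  }
  k <- length(class_sizes)
  class_names <- class_names %||% paste0("FN", seq_len(k))
  if (length(class_names) != k) stop("need one name per class")
  region_ids <- region_ids %||% paste0("R", seq_len(n_regions))
  sigma <- rep(seq_len(k), class_sizes)
  names(sigma) <- region_ids
  structure(list(sigma = sigma, k = k, class_names = class_names,
                 region_ids = region_ids),
            class = "fn_partition")
}

#' Partition from per-region labels
#'
#' @param labels character/factor vector of class labels, one per region.
#' @param region_ids optional region labels (defaults to names of `labels`).
#' @param class_names optional explicit class order (defaults to order of
#'   first appearance).
#' @return an `fn_partition`.
#' @export
fn_partition <- function(labels, region_ids = NULL, class_names = NULL) {
  labels <- as.character(labels)
  region_ids <- region_ids %||% names(labels) %||% paste0("R", seq_along(labels))
  class_names <- class_names %||% unique(labels)
  if (!all(labels %in% class_names)) {
    stop("labels contain classes not in class_names: ",
         paste(setdiff(labels, class_names), collapse = ", "))
  }
  if (!all(class_names %in% labels)) stop("every class must be non-empty")
  sigma <- match(labels, class_names)
  names(sigma) <- region_ids
  structure(list(sigma = sigma, k = length(class_names),
                 class_names = class_names, region_ids = region_ids),
            class = "fn_partition")
}

#' @export
print.fn_partition <- function(x, ...) {
  cat("<fn_partition> ", length(x$sigma), " regions in ", x$k, " classes: ",
      paste0(x$class_names, " (", tabulate(x$sigma, x$k), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

.check_partition_matches <- function(fc, part) {
  if (length(part$sigma) != nrow(fc)) {
    stop("partition covers ", length(part$sigma), " regions but connectome has ",
         nrow(fc))
  }
  if (!is.null(rownames(fc)) && !identical(part$region_ids, rownames(fc))) {
    stop("partition region_ids do not match connectome region order")
  }
  invisible(TRUE)
}

#' Induced sub-connectome of one functional network
#'
#' Principal submatrix of the connectome on the regions of one partition
#' class, region order preserved.
#'
#' @param fc an [fc_matrix()].
#' @param part an `fn_partition`.
#' @param class_id class label (in `part$class_names`) or class index.
#' @return an [fc_matrix()] on the class's regions.
#' @export
induced_subnetwork <- function(fc, part, class_id) {
  .check_partition_matches(fc, part)
  if (is.character(class_id)) {
    ci <- match(class_id, part$class_names)
    if (is.na(ci)) stop("unknown class: ", class_id)
  } else {
    ci <- as.integer(class_id)
    if (ci < 1 || ci > part$k) stop("unknown class index: ", class_id)
  }
  idx <- which(part$sigma == ci)
  sub <- unclass(fc)[idx, idx, drop = FALSE]
  fc_matrix(sub, part$region_ids[idx])
}

#' Consolidated super-graph of a partitioned connectome
#'
#' Contracts every functional network to a single super-node. The raw
#' cross-class weight is the double sum `W_ij = sum_{u in i, v in j} w_uv`;
#' off-diagonal entries are then normalized by their maximum so the largest
#' cross-class coupling is exactly 1, and the diagonal is set to 1 so the
#' normalized super-graph is itself a valid connectome to which all
#' homological operations apply.
#'
#' @param fc an [fc_matrix()].
#' @param part an `fn_partition` covering all regions.
#' @return object of class `super_graph`: list with `raw` (k x k block sums;
#'   diagonal holds within-class sums), `normalized` (an [fc_matrix()] on the
#'   class names) and `class_names`.
#' @export
consolidate_supergraph <- function(fc, part) {
  .check_partition_matches(fc, part)
  W <- unclass(fc)
  k <- part$k
  B <- matrix(0, nrow(W), k)
  B[cbind(seq_len(nrow(W)), part$sigma)] <- 1
  S <- t(B) %*% W %*% B
  dimnames(S) <- list(part$class_names, part$class_names)
  off <- S[upper.tri(S) | lower.tri(S)]
  mx <- max(off)
  Nrm <- S
  if (mx == 0) {
    warning("all cross-class weights are zero; normalized super-graph is zero off-diagonal")
    Nrm[upper.tri(Nrm) | lower.tri(Nrm)] <- 0
  } else {
    Nrm <- S / mx
  }
  diag(Nrm) <- 1
  structure(list(raw = S, normalized = fc_matrix(Nrm, part$class_names),
                 class_names = part$class_names),
            class = "super_graph")
}

#' @export
print.super_graph <- function(x, ...) {
  cat("<super_graph> ", length(x$class_names), " super-nodes: ",
      paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}
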