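#' Pairwise diagram-distance table across conditions
#'
#' Builds the symmetric condition-by-condition matrix of diagram distances
#' for one homological dimension. The default metric follows the usual
#' binding: Hausdorff on death values for H0 (where every class is born at
#' 0 and Wasserstein matching degenerates), q-Wasserstein for H1/H2.
#'
#' @param diagrams named list of `persistence_diagrams`, one per condition.
#' @param dim homological dimension.
#' @param metric `"auto"` (Hausdorff for dim 0, Wasserstein otherwise),
#'   `"hausdorff"` or `"wasserstein"`.
#' @param q Wasserstein order (> 1).
#' @param drop_zero drop zero-persistence intervals before Wasserstein.
#' @return symmetric matrix of class `distance_table` with attributes
#'   `metric`, `dimension`, `q`.
#' @export
pairwise_distance_table <- function(diagrams, dim, metric = c("auto", "hausdorff", "wasserstein"),
                                    q = 2, drop_zero = TRUE) {
  metric <- match.arg(metric)
  labels <- names(diagrams)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("diagrams must be a named list with unique condition labels")
  }
  if (metric == "auto") metric <- if (dim == 0) "hausdorff" else "wasserstein"
  for (lab in labels) {
    d <- diagrams[[lab]]
    if (!"dimension" %in% names(d) || !any(d$dimension == dim)) {
      if (dim == 0) stop("missing H0 diagram for condition ", lab)
      # empty H1/H2 diagrams are legitimate (e.g. small consolidated graphs)
    }
  }
  k <- length(labels)
  M <- matrix(0, k, k, dimnames = list(labels, labels))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        M[i, j] <- M[j, i] <- .diagram_distance(diagrams[[i]], diagrams[[j]],
                                                dim, metric, q, drop_zero)
      }
    }
  }
  structure(M, metric = paste0(metric, if (metric == "wasserstein") paste0("_q", q)),
            dimension = dim, q = q, class = c("distance_table", "matrix", "array"))
}

.diagram_distance <- function(dx, dy, dim, metric, q, drop_zero = TRUE) {
  if (metric == "hausdorff") {
    hausdorff_h0_distance(dx[dx$dimension == dim, , drop = FALSE],
                          dy[dy$dimension == dim, , drop = FALSE])
  } else {
    wasserstein_distance(dx, dy, q = q, dim = dim, drop_zero = drop_zero)
  }
}

#' Per-condition distance profiles and the most distinct pair
#'
#' For each condition: the mean and the population variance of its
#' distances to all other conditions (diagonal excluded), plus the
#' unordered pair with the largest distance. Ties are broken by the
#' lexicographically smallest (labelA, labelB) pair, labels sorted within
#' the pair, so the result is deterministic.
#'
#' @param tbl a [pairwise_distance_table()].
#' @return list with `means`, `variances` (named vectors),
#'   `most_distinct_pair` (character 2-vector) and `max_value`.
#' @export
condition_profiles <- function(tbl) {
  labels <- rownames(tbl)
  k <- length(labels)
  if (k < 2) stop("need at least 2 conditions")
  M <- unclass(tbl)
  means <- rowSums(M) / (k - 1)
  variances <- vapply(seq_len(k), function(i) {
    x <- M[i, -i]
    mean((x - mean(x))^2)
  }, 0)
  names(means) <- names(variances) <- labels
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[ut]
  cand <- ut[vals == max(vals), , drop = FALSE]
  pairs <- apply(cand, 1, function(ij) sort(labels[ij]))
  ord <- order(pairs[1, ], pairs[2, ])
  best <- pairs[, ord[1]]
  list(means = means, variances = variances,
       most_distinct_pair = best, max_value = max(vals))
}

#' Consensus vote over subjects' most distinct pairs
#'
#' Each subject's distance table votes for its most distinct condition
#' pair; counts over all subjects land in the upper triangle and always sum
#' to the number of subjects.
#'
#' @param tables list of [pairwise_distance_table()] objects, one per
#'   subject, sharing condition labels.
#' @return upper-triangular integer matrix of class `consensus_count` with
#'   attribute `n_subjects`.
#' @export
consensus_vote <- function(tables) {
  if (length(tables) == 0) stop("no subject tables")
  labels <- rownames(tables[[1]])
  C <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (tbl in tables) {
    if (!identical(rownames(tbl), labels)) stop("condition labels differ across subjects")
    pair <- condition_profiles(tbl)$most_distinct_pair
    ij <- sort(match(pair, labels))
    C[ij[1], ij[2]] <- C[ij[1], ij[2]] + 1L
  }
  structure(C, n_subjects = length(tables),
            class = c("consensus_count", "matrix", "array"))
}

#' Per-subject distances between a task and rest for one functional network
#'
#' For every subject, the diagram distance between that subject's
#' (network, task) diagram and its (network, rest) diagram, in subject
#' order.
#'
#' @param subject_diagrams nested named list:
#'   `subject -> functional network -> condition -> persistence_diagrams`.
#' @param fn functional-network label.
#' @param task condition label to compare against rest.
#' @param dim homological dimension.
#' @param metric,q,drop_zero as in [pairwise_distance_table()].
#' @param rest label of the rest condition (default `"REST"`).
#' @return named numeric vector, one distance per subject.
#' @export
all_to_rest_distances <- function(subject_diagrams, fn, task, dim,
                                  metric = c("auto", "hausdorff", "wasserstein"),
                                  q = 2, drop_zero = TRUE, rest = "REST") {
  metric <- match.arg(metric)
  if (metric == "auto") metric <- if (dim == 0) "hausdorff" else "wasserstein"
  subjects <- names(subject_diagrams)
  vapply(subjects, function(s) {
    per_fn <- subject_diagrams[[s]][[fn]]
    if (is.null(per_fn)) stop("missing network ", fn, " for subject ", s)
    dx <- per_fn[[task]]
    dr <- per_fn[[rest]]
    if (is.null(dx)) stop("missing condition ", task, " for subject ", s)
    if (is.null(dr)) stop("missing condition ", rest, " for subject ", s)
    .diagram_distance(dx, dr, dim, metric, q, drop_zero)
  }, 0)
}

#' Kullback-Leibler divergence between two samples
#'
#' Histogram estimator on a shared equal-width grid spanning the pooled
#' range of both samples; a pseudocount is added to every bin before
#' normalizing, then `KL(P || Q) = sum p_i log(p_i / q_i)` (natural log).
#' Asymmetric in its arguments, as KL divergence is. A degenerate pooled
#' range (all values identical) returns 0.
#'
#' @param p_samples,q_samples non-empty numeric vectors.
#' @param bins number of histogram bins (default 10).
#' @param pseudocount added to every bin (default 1); with 0, bins where
#'   `p_i = 0` contribute 0 and `q_i = 0 < p_i` yields `Inf`.
#' @return nonnegative numeric (possibly `Inf` when `pseudocount = 0`).
#' @export
kl_divergence <- function(p_samples, q_samples, bins = 10, pseudocount = 1) {
  if (length(p_samples) == 0 || length(q_samples) == 0) stop("empty sample")
  rng <- range(c(p_samples, q_samples))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  hist_counts <- function(x) {
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE),
             nbins = bins)
  }
  p <- hist_counts(p_samples) + pseudocount
  q <- hist_counts(q_samples) + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  terms <- ifelse(p > 0, p * log(p / q), 0)
  sum(terms)
}

#' Top-k functional-network pairs by divergence
#'
#' Ranks the `k` largest entries of a network-pair table in decreasing
#' order and normalizes their strengths by the largest selected value (top
#' entry = 1). Symmetric tables are scanned over unordered pairs (upper
#' triangle); asymmetric tables over all ordered off-diagonal pairs. Ties
#' are broken by the lexicographically smallest label pair.
#'
#' @param kl_table square matrix with network labels as dimnames.
#' @param k number of pairs to keep, `1 <= k <=` number of pairs.
#' @return data frame with columns `fn_a`, `fn_b`, `value`, `strength`.
#' @export
top_k_fn_pairs <- function(kl_table, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be a positive integer")
  labels <- rownames(kl_table)
  M <- unclass(kl_table)
  sym <- isSymmetric(unname(M))
  idx <- if (sym) which(upper.tri(M), arr.ind = TRUE) else
    which(row(M) != col(M), arr.ind = TRUE)
  if (k > nrow(idx)) stop("k = ", k, " exceeds the number of pairs (", nrow(idx), ")")
  df <- data.frame(fn_a = labels[idx[, 1]], fn_b = labels[idx[, 2]],
                   value = M[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$value, df$fn_a, df$fn_b), , drop = FALSE]
  df <- df[seq_len(k), , drop = FALSE]
  mx <- max(df$value)
  df$strength <- if (mx > 0) df$value / mx else 0
  rownames(df) <- NULL
  df
}
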