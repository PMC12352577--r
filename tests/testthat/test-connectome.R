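test_that("fc_matrix enforces symmetry, range and unit diagonal", {
  W <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_s3_class(fc_matrix(W), "fc_matrix")

  A <- W; A[1, 2] <- 0.7
  expect_error(fc_matrix(A), "asymmetric")
  B <- W; B[1, 2] <- B[2, 1] <- 1.5
  expect_error(fc_matrix(B), "\\[0, 1\\]")
  C <- W; diag(C) <- 0.9
  expect_error(fc_matrix(C), "diagonal")
  # sub-tolerance asymmetry is repaired by averaging
  D <- W; D[1, 2] <- 0.5 + 1e-10
  expect_equal(unclass(fc_matrix(D))[1, 2], unclass(fc_matrix(D))[2, 1])
})

test_that("fc_from_timeseries takes absolute Pearson correlations", {
  set.seed(1)
  x <- rnorm(100)
  ts <- rbind(a = x, b = 2 * x + 3, c = -x)
  fc <- fc_from_timeseries(ts)
  expect_equal(unclass(fc)[1, 2], 1)        # perfectly correlated
  expect_equal(unclass(fc)[1, 3], 1)        # anti-correlated, |-1| = 1
  expect_equal(diag(unclass(fc)), c(a = 1, b = 1, c = 1))

  ts2 <- rbind(a = x, flatline = rep(2, 100))
  expect_error(fc_from_timeseries(ts2), "flatline")
})

test_that("planted pairwise correlation is recovered from long series", {
  set.seed(42)
  n_t <- 10000
  z <- rnorm(n_t)
  # three series with pairwise correlation 0.5 via a shared factor
  ts <- t(sapply(1:3, function(i) sqrt(0.5) * z + sqrt(0.5) * rnorm(n_t)))
  fc <- fc_from_timeseries(ts)
  off <- unclass(fc)[upper.tri(fc)]
  expect_true(all(abs(off - 0.5) < 0.02))
})

test_that("group averaging is the entrywise mean with unit diagonal", {
  set.seed(2)
  fc <- random_fc(5)
  expect_equal(unclass(group_average_fc(list(fc, fc, fc))), unclass(fc))

  W1 <- matrix(0.4, 3, 3); diag(W1) <- 1
  W2 <- matrix(0.8, 3, 3); diag(W2) <- 1
  avg <- group_average_fc(list(fc_matrix(W1), fc_matrix(W2)))
  expect_equal(unclass(avg)[1, 2], 0.6)

  expect_error(group_average_fc(list()), "empty")
  other <- fc_matrix(unclass(fc), region_ids = paste0("X", 1:5))
  expect_error(group_average_fc(list(fc, other)), "mismatched")
})

test_that("group mean concentrates on the common structure", {
  set.seed(3)
  n <- 6
  base <- matrix(0.5, n, n); diag(base) <- 1
  eps <- 0.05
  subs <- lapply(1:100, function(i) {
    E <- matrix(runif(n * n, -eps, eps), n)
    E <- (E + t(E)) / 2; diag(E) <- 0
    fc_matrix(base + E)
  })
  avg <- group_average_fc(subs)
  se <- (eps / sqrt(3)) / sqrt(100)   # sd of U(-eps, eps) over 100 subjects
  expect_true(all(abs(unclass(avg)[upper.tri(avg)] - 0.5) < 3 * se))
})

test_that("dissimilarity is the involution 1 - w with zero diagonal", {
  set.seed(4)
  fc <- random_fc(6)
  D <- dissimilarity_matrix(fc)
  expect_equal(diag(unclass(D)), rep(0, 6), ignore_attr = TRUE)
  expect_equal(unclass(D)[1, 2], 1 - unclass(fc)[1, 2])
  expect_equal(1 - unclass(D) + diag(0, 6), unclass(fc) - diag(0, 6),
               ignore_attr = TRUE)
})

test_that("weight_levels dedupes and sorts decreasing", {
  W <- matrix(0.5, 4, 4); diag(W) <- 1
  expect_equal(weight_levels(fc_matrix(W)), 0.5)

  W2 <- matrix(c(1, 0.2, 0.9, 0.2, 1, 0.2, 0.9, 0.2, 1), 3)
  expect_equal(weight_levels(fc_matrix(W2)), c(0.9, 0.2))

  lv <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  W3 <- matrix(0, 5, 5)
  W3[upper.tri(W3)] <- rep_len(lv, 10)
  W3 <- W3 + t(W3); diag(W3) <- 1
  expect_length(weight_levels(fc_matrix(W3)), 5)
})

test_that("threshold graphs keep edges with w >= r and are nested", {
  set.seed(5)
  fc <- random_fc(8)
  expect_equal(nrow(threshold_graph(fc, 0)$edges), 8 * 7 / 2)
  expect_equal(nrow(threshold_graph(fc, max(weight_levels(fc)) + 1e-9)$edges), 0)
  r <- median(unclass(fc)[upper.tri(fc)])
  g <- threshold_graph(fc, r)
  expect_equal(nrow(g$edges), sum(unclass(fc)[upper.tri(fc)] >= r))
  # ties at w == r are included
  W <- matrix(0.5, 3, 3); diag(W) <- 1
  expect_equal(nrow(threshold_graph(fc_matrix(W), 0.5)$edges), 3)
  # nesting across all weight levels
  lv <- weight_levels(fc)
  for (i in seq_len(length(lv) - 1)) {
    e_hi <- threshold_graph(fc, lv[i])$edges
    e_lo <- threshold_graph(fc, lv[i + 1])$edges
    key <- function(e) paste(e[, 1], e[, 2])
    expect_true(all(key(e_hi) %in% key(e_lo)))
  }
  expect_error(threshold_graph(fc, 1.2), "\\[0, 1\\]")
})

test_that("graph Betti numbers satisfy known values and the Euler identity", {
  set.seed(6)
  fc <- random_fc(5)
  empty <- threshold_graph(fc, 1)
  expect_equal(graph_betti(empty), c(b0 = 5L, b1 = 0L))
  complete <- threshold_graph(fc, 0)
  expect_equal(graph_betti(complete), c(b0 = 1L, b1 = 6L))
  for (i in 1:50) {
    g <- threshold_graph(random_fc(10), runif(1))
    b <- graph_betti(g)
    expect_identical(unname(b["b0"] - b["b1"]), 10L - nrow(g$edges))
    expect_gte(b["b1"], 0L)
  }
})

test_that("induced subnetworks are principal submatrices", {
  set.seed(7)
  fc <- random_fc(12)
  part <- make_partition(12, c(5, 4, 3))
  expect_equal(unclass(induced_subnetwork(fc, make_partition(12, 12), 1)),
               unclass(fc))
  p1 <- make_partition(12, c(1, 11))
  expect_equal(unclass(induced_subnetwork(fc, p1, 1)),
               matrix(1, 1, 1, dimnames = list("R1", "R1")))
  sub <- induced_subnetwork(fc, part, 2)
  idx <- 6:9
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    expect_identical(unclass(sub)[i, j], unclass(fc)[idx[i], idx[j]])
  }
  expect_error(induced_subnetwork(fc, part, "nope"), "unknown class")
  # nested induction equals direct induction on the intersection
  sub2 <- induced_subnetwork(sub, make_partition(4, c(2, 2),
                                                 region_ids = rownames(sub)), 1)
  direct <- unclass(fc)[6:7, 6:7]
  expect_equal(unclass(sub2), direct, ignore_attr = TRUE)
})

test_that("consolidation sums cross-class weights and max-normalizes", {
  ex <- example_connectome()
  sg <- consolidate_supergraph(ex$fc, ex$partition)
  expect_equal(length(sg$class_names), 3)
  expect_equal(dim(sg$normalized), c(3, 3))

  # all cross weights equal -> normalized off-diagonal exactly 1
  W <- matrix(0.3, 4, 4); diag(W) <- 1
  sg2 <- consolidate_supergraph(fc_matrix(W), make_partition(4, c(2, 2)))
  expect_equal(unclass(sg2$normalized)[1, 2], 1)

  # brute-force double sum oracle
  set.seed(8)
  fc <- random_fc(10)
  part <- make_partition(10, c(4, 3, 3))
  sg3 <- consolidate_supergraph(fc, part)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    s <- 0
    for (u in which(part$sigma == i)) for (v in which(part$sigma == j)) {
      s <- s + unclass(fc)[u, v]
    }
    expect_equal(sg3$raw[i, j], s)
  }
  # normalized entries are scale-invariant in the cross-class weights
  W4 <- unclass(fc)
  blocks <- outer(part$sigma, part$sigma, "!=")
  W4[blocks] <- W4[blocks] * 0.5
  sg4 <- consolidate_supergraph(fc_matrix(W4), part)
  expect_equal(unclass(sg4$normalized), unclass(sg3$normalized))
  expect_equal(max(unclass(sg3$normalized)[upper.tri(sg3$normalized)]), 1)

  # no cross-class coupling at all: zeros plus a warning
  W5 <- matrix(0, 4, 4)
  W5[1, 2] <- W5[2, 1] <- 0.9
  W5[3, 4] <- W5[4, 3] <- 0.8
  diag(W5) <- 1
  expect_warning(sg5 <- consolidate_supergraph(fc_matrix(W5),
                                               make_partition(4, c(2, 2))),
                 "zero")
  expect_equal(unclass(sg5$normalized)[1, 2], 0)
})
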