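test_that("flag filtration inserts cliques at their max pairwise dissimilarity", {
  # single triangle, all d = 0.4
  W <- matrix(0.6, 3, 3); diag(W) <- 1
  fx <- build_flag_filtration(dissimilarity_matrix(fc_matrix(W)), max_dim = 2)
  expect_equal(sum(fx$dim == 0), 3)
  expect_equal(sum(fx$dim == 1), 3)
  expect_equal(sum(fx$dim == 2), 1)
  expect_equal(fx$filt[fx$dim == 0], rep(0, 3))
  expect_equal(fx$filt[fx$dim == 1], rep(0.4, 3))
  expect_equal(fx$filt[fx$dim == 2], 0.4)

  # 4-cycle with cheap cycle edges and expensive chords: triangles at 0.9
  W2 <- matrix(0, 4, 4)
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))
  W2[cyc] <- 0.8; W2 <- W2 + t(W2)
  W2[1, 3] <- W2[3, 1] <- 0.1
  W2[2, 4] <- W2[4, 2] <- 0.1
  diag(W2) <- 1
  fx2 <- build_flag_filtration(dissimilarity_matrix(fc_matrix(W2)), max_dim = 2)
  expect_equal(fx2$filt[fx2$dim == 2], rep(0.9, 4))

  # complete complex has every clique up to the dimension cap
  set.seed(11)
  fc <- random_fc(7)
  fx3 <- build_flag_filtration(dissimilarity_matrix(fc), max_dim = 3)
  expect_equal(length(fx3$filt), 7 + choose(7, 2) + choose(7, 3) + choose(7, 4))
  expect_error(build_flag_filtration(dissimilarity_matrix(fc), max_dim = 4),
               "max_dim")
  expect_error(build_flag_filtration(dissimilarity_matrix(fc), max_dim = 3,
                                     n_cap = 5), "cap")
})

test_that("filtration order always places faces before cofaces", {
  set.seed(12)
  for (rep in 1:5) {
    fx <- build_flag_filtration(dissimilarity_matrix(random_fc(6)), max_dim = 3)
    seen <- character(0)
    m <- length(fx$filt)
    for (j in seq_len(m)) {
      v <- fx$verts[(fx$offsets[j] + 1):fx$offsets[j + 1]]
      if (length(v) > 1) {
        for (drop in seq_along(v)) {
          expect_true(paste(v[-drop], collapse = "-") %in% seen)
        }
      }
      seen <- c(seen, paste(v, collapse = "-"))
    }
    expect_true(!is.unsorted(fx$filt))
  }
})

test_that("persistence of a discrete set: n classes born at 0, one essential", {
  W <- diag(5)  # off-diagonal weight 0, i.e. d = 1 everywhere
  dg <- persistence_of(fc_matrix(W))
  h0 <- dg[dg$dimension == 0, ]
  expect_equal(nrow(h0), 5)
  expect_equal(h0$birth, rep(0, 5))
  expect_equal(sum(h0$essential), 1)
  expect_equal(h0$death[h0$essential], 1.0)
})

test_that("a 4-cycle yields the H1 interval (0.3, 1.0)", {
  W <- matrix(0, 4, 4)
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))
  W[cyc] <- 0.7; W <- W + t(W); diag(W) <- 1   # cycle edges d = 0.3, chords d = 1
  dg <- persistence_of(fc_matrix(W))
  h1 <- dg[dg$dimension == 1 & dg$death > dg$birth, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 0.3)
  expect_equal(h1$death, 1.0)
  expect_false(h1$essential)
})

test_that("the worked example reproduces its Betti sequences and H1 bars", {
  ex <- example_connectome()
  dg <- persistence_of(ex$fc)
  bc <- betti_curve(dg, sort(1 - ex$stage_r))
  expect_equal(bc$betti[bc$dimension == 0], c(10, 6, 3, 3, 3, 1))
  expect_equal(bc$betti[bc$dimension == 1], c(0, 1, 2, 1, 0, 0))
  h1 <- dg[dg$dimension == 1 & dg$death > dg$birth, ]
  expect_equal(nrow(h1), 2)
  # the FN2 5-cycle (0.1, 0.6) outlives the FN3 4-cycle (0.3, 0.5)
  persist <- h1$death - h1$birth
  expect_equal(h1$birth[which.max(persist)], 0.1)
  expect_equal(h1$death[which.max(persist)], 0.6)
  expect_equal(h1$birth[which.min(persist)], 0.3)
  expect_equal(h1$death[which.min(persist)], 0.5)
})

test_that("H0 intervals number exactly n with a single essential class", {
  set.seed(13)
  for (n in c(4, 7, 10)) {
    dg <- persistence_of(random_fc(n))
    h0 <- dg[dg$dimension == 0, ]
    expect_equal(nrow(h0), n)
    expect_equal(sum(h0$essential), 1)
    expect_true(all(h0$death <= 1))
    h1 <- dg[dg$dimension == 1, ]
    expect_true(all(!h1$essential))
  }
})

test_that("diagram Betti curves agree with the boundary-rank oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    fc <- random_fc(n)
    D <- dissimilarity_matrix(fc)
    dg <- compute_persistence(build_flag_filtration(D, 3))
    ts <- sort(unique(unclass(D)[upper.tri(D)]))
    for (p in 0:2) {
      bc <- betti_curve(dg, ts, dims = p)$betti
      oracle <- vapply(ts, function(t) brute_force_betti(D, t, p), 0L)
      expect_identical(bc, oracle)
    }
  }
})

test_that("the hollow octahedron carries one 2-cycle", {
  # 6 points, antipodal pairs far (d = 0.9), all other pairs near (d = 0.2)
  D <- matrix(0.2, 6, 6)
  D[1, 2] <- D[2, 1] <- 0.9
  D[3, 4] <- D[4, 3] <- 0.9
  D[5, 6] <- D[6, 5] <- 0.9
  diag(D) <- 0
  fc <- fc_matrix(1 - D + diag(0, 6))
  Dm <- dissimilarity_matrix(fc)
  expect_identical(brute_force_betti(Dm, 0.5, 2), 1L)
  expect_identical(brute_force_betti(Dm, 0.5, 1), 0L)
  dg <- compute_persistence(build_flag_filtration(Dm, 3))
  h2 <- dg[dg$dimension == 2 & dg$death > dg$birth, ]
  expect_equal(nrow(h2), 1)
  expect_equal(h2$birth, 0.2)
  expect_equal(h2$death, 0.9)
  # the full simplex at the end is contractible
  expect_identical(brute_force_betti(Dm, 1, 1), 0L)
  expect_identical(brute_force_betti(Dm, 1, 2), 0L)
})

test_that("H0 deaths are 1-Lipschitz in the edge weights", {
  set.seed(15)
  for (eps in c(0.01, 0.05)) {
    for (rep in 1:5) {
      fc <- random_fc(10)
      d0 <- sort(diagram(persistence_of(fc, 1), 0)$death)
      P <- matrix(runif(100, -eps, eps), 10)
      P <- (P + t(P)) / 2; diag(P) <- 0
      W2 <- clamp_weights(unclass(fc) + P)
      d1 <- sort(diagram(persistence_of(fc_matrix(W2), 1), 0)$death)
      expect_lte(max(abs(d0 - d1)), eps + 1e-12)
    }
  }
})

test_that("graph b1 and complex b1 part ways once triangles fill", {
  W <- matrix(0.8, 3, 3); diag(W) <- 1  # one triangle at d = 0.2
  fc <- fc_matrix(W)
  gb <- graph_betti(threshold_graph(fc, 0.8))
  expect_equal(unname(gb["b1"]), 1L)     # the graph sees a 3-cycle
  dg <- persistence_of(fc)
  bc <- betti_curve(dg, 0.2, dims = 1)
  expect_equal(bc$betti, 0L)             # the filled triangle has no hole
})

test_that("an invalid filtration order is rejected", {
  fx <- build_flag_filtration(dissimilarity_matrix(fc_matrix(diag(3))), 1)
  broken <- fx
  ord <- rev(seq_along(fx$filt))
  # rebuild flat representation in reversed (invalid) order
  vlist <- lapply(seq_along(fx$filt), function(j) {
    fx$verts[(fx$offsets[j] + 1):fx$offsets[j + 1]]
  })[ord]
  broken$verts <- as.integer(unlist(vlist))
  broken$offsets <- as.integer(c(0, cumsum(lengths(vlist))))
  broken$filt <- fx$filt[ord]
  broken$dim <- fx$dim[ord]
  expect_error(compute_persistence(broken), "filtration order")
})
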