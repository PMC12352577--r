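# shared fixture builders; all randomness is seeded by the caller

random_fc <- function(n) {
  W <- matrix(runif(n * n), n)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  fc_matrix(W)
}

# random diagram as a (birth, death) matrix with values in [0, 1]
random_intervals <- function(n) {
  b <- runif(n)
  cbind(b, b + runif(n) * (1 - b))
}

clamp_weights <- function(W) {
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 1
  (W + t(W)) / 2
}

persistence_of <- function(fc, max_dim = 2) {
  compute_persistence(build_flag_filtration(dissimilarity_matrix(fc), max_dim))
}

# tiny cohort spec for fast end-to-end tests
tiny_spec <- function(seed, n_subjects = 3) {
  cohort_spec(n_subjects = n_subjects, n_regions = 12,
              class_sizes = c(4, 4, 4), class_names = c("VIS", "SM", "DA"),
              n_timepoints = 60, conditions = c("REST", "MOT"),
              task_effects = list(MOT = c(SM = 0.8)), seed = seed)
}
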