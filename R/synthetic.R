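#' Specification of a synthetic modular cohort
#'
#' Describes a cohort of subjects scanned under several conditions, with
#' regions grouped into functional networks (FNs) by a block partition.
#' Regional signals follow a linear latent-factor model: each region loads
#' on its network's factor (within-network coupling `lambda_i`), on one
#' global factor (between-network coupling), and carries unit-variance
#' noise, so pairwise correlations have closed forms usable as analytic
#' oracles -- at rest, same-network pairs correlate at
#' `(lambda^2 + g^2) / (lambda^2 + g^2 + 1)`, different-network pairs only
#' through the global factor.
#'
#' A task perturbation `delta` on a network does two things: it strengthens
#' the network's shared factor (loading `lambda + 0.3 delta`) and it
#' reorganizes the network into a cyclic coordination pattern -- regions
#' additionally load, with phases equally spaced around a circle, on a pair
#' of ring factors with amplitude `delta`. The strengthening raises the
#' mean within-network weight (an H0-visible merge-height shift); the ring
#' plants a genuine persistent 1-cycle (an H1-visible loop). Rest is the
#' unperturbed baseline.
#'
#' The defaults describe the package's reference desk-scale cohort:
#' 20 subjects, 40 regions in 5 networks (10/10/8/6/6), 300 timepoints,
#' conditions REST/EMOT/WM/MOT. All three tasks share a common engagement
#' perturbation of the dorsal-attention network (`DA = 0.7`); the motor
#' condition additionally reorganizes the somatomotor network
#' (`SM = 0.9`). Tasks therefore cluster together away from rest, and the
#' most perturbed condition (MOT) is farthest from rest in particular --
#' the planted effect every pipeline level should recover.
#'
#' @param n_subjects,n_regions,n_timepoints cohort dimensions.
#' @param class_sizes,class_names block partition of the regions into FNs.
#' @param conditions condition labels; must include `"REST"`.
#' @param within_coupling baseline within-network factor loading(s), in
#'   (0, 1); recycled to one per network.
#' @param between_coupling global factor loading shared by all regions.
#' @param task_effects named list: condition -> named numeric vector of
#'   per-network loading perturbations. REST must not appear.
#' @param subject_sd sd of the per-subject jitter applied once per subject
#'   to each network's within-loading.
#' @param seed integer seed; required, no silent default.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, n_regions = 40,
                        class_sizes = c(10, 10, 8, 6, 6),
                        class_names = c("VIS", "SM", "DA", "LIM", "DMN"),
                        n_timepoints = 300,
                        conditions = c("REST", "EMOT", "WM", "MOT"),
                        within_coupling = 0.4,
                        between_coupling = 0.15,
                        task_effects = list(EMOT = c(DA = 0.7),
                                            WM = c(DA = 0.7),
                                            MOT = c(DA = 0.7, SM = 0.9)),
                        subject_sd = 0.05,
                        seed) {
  if (missing(seed)) stop("seed is required (no silent default)")
  if (!"REST" %in% conditions) stop("conditions must include REST")
  if ("REST" %in% names(task_effects)) stop("REST must have zero perturbation")
  if (!all(names(task_effects) %in% conditions)) {
    stop("task_effects name unknown conditions: ",
         paste(setdiff(names(task_effects), conditions), collapse = ", "))
  }
  k <- length(class_sizes)
  within <- rep_len(within_coupling, k)
  names(within) <- class_names
  if (any(within <= 0 | within >= 1)) stop("within_coupling must lie in (0, 1)")
  if (between_coupling < 0 || between_coupling >= 1) {
    stop("between_coupling must lie in [0, 1)")
  }
  for (cond in names(task_effects)) {
    eff <- task_effects[[cond]]
    if (!all(names(eff) %in% class_names)) {
      stop("task_effects for ", cond, " name unknown networks")
    }
    if (any(eff < 0)) stop("task_effects must be nonnegative")
    lam <- within
    lam[names(eff)] <- lam[names(eff)] + 0.3 * eff
    if (any(lam >= 1)) {
      stop("perturbed loadings for ", cond, " leave (0, 1)")
    }
  }
  part <- make_partition(n_regions, class_sizes, class_names)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 partition = part,
                 n_timepoints = as.integer(n_timepoints),
                 conditions = conditions,
                 within_coupling = within,
                 between_coupling = between_coupling,
                 task_effects = task_effects,
                 subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of functional connectomes
#'
#' Draws, for every subject and condition, regional time series from the
#' latent-factor model described in [cohort_spec()] and converts them to
#' connectomes via [fc_from_timeseries()] (so synthetic and real data share
#' the estimation path). The per-subject loading jitter is drawn once per
#' subject and applied across all of that subject's conditions. Fully
#' reproducible: identical specs (including seed) give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `fc_cohort`: list with `fcs` (nested list
#'   `subject -> condition -> fc_matrix`), `partition`, `truth` (a
#'   `planted_truth` list: `most_perturbed_condition`, `most_perturbed_fn`,
#'   `effects`) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(spec$seed)
  part <- spec$partition
  sigma <- part$sigma
  n <- spec$n_regions
  Tn <- spec$n_timepoints
  k <- part$k
  g <- spec$between_coupling

  totals <- vapply(spec$task_effects, function(e) sum(abs(e)), 0)
  most_cond <- if (length(totals)) names(totals)[which.max(totals)] else NA_character_
  most_fn <- if (length(totals)) {
    eff <- spec$task_effects[[most_cond]]
    names(eff)[which.max(abs(eff))]
  } else NA_character_
  truth <- structure(list(most_perturbed_condition = most_cond,
                          most_perturbed_fn = most_fn,
                          effects = spec$task_effects),
                     class = "planted_truth")

  subjects <- sprintf("S%03d", seq_len(spec$n_subjects))
  fcs <- vector("list", spec$n_subjects)
  names(fcs) <- subjects
  for (s in seq_len(spec$n_subjects)) {
    jitter <- rnorm(k, 0, spec$subject_sd)
    per_cond <- vector("list", length(spec$conditions))
    names(per_cond) <- spec$conditions
    for (cond in spec$conditions) {
      eff <- spec$task_effects[[cond]]
      delta <- setNames(numeric(k), part$class_names)
      if (!is.null(eff)) delta[names(eff)] <- eff
      # task engagement strengthens the network's shared factor a little and
      # reorganizes it into a cyclic coordination pattern (ring factor pair),
      # so the perturbation is visible to H0 (merge heights) and H1 (a
      # planted persistent loop) alike
      lam <- .clamp(spec$within_coupling + jitter + 0.3 * delta, 0.01, 0.99)
      Fk <- matrix(rnorm(k * Tn), k, Tn)          # network factors
      gl <- rnorm(Tn)                             # global factor
      E <- matrix(rnorm(n * Tn), n, Tn)           # idiosyncratic noise
      X <- lam[sigma] * Fk[sigma, , drop = FALSE] +
        g * matrix(gl, n, Tn, byrow = TRUE) + E
      for (ci in which(delta > 0)) {
        idx <- which(sigma == ci)
        th <- 2 * pi * (seq_along(idx) - 1) / length(idx)
        r1 <- rnorm(Tn)
        r2 <- rnorm(Tn)
        X[idx, ] <- X[idx, ] + delta[ci] * (cos(th) %o% r1 + sin(th) %o% r2)
      }
      rownames(X) <- part$region_ids
      per_cond[[cond]] <- fc_from_timeseries(X)
    }
    fcs[[s]] <- per_cond
  }
  structure(list(fcs = fcs, partition = part, truth = truth, spec = spec),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat("<fc_cohort> ", length(x$fcs), " subjects x ",
      length(x$spec$conditions), " conditions, ", x$spec$n_regions,
      " regions in ", x$partition$k, " networks\n", sep = "")
  invisible(x)
}

#' Write a cohort to disk in the package's text formats
#'
#' One connectome CSV per (subject, condition), the partition as a
#' two-column table, and a JSON truth manifest.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (s in names(cohort$fcs)) {
    for (cond in names(cohort$fcs[[s]])) {
      f <- file.path(dir, paste0(s, "_", cond, ".csv"))
      write_fc(cohort$fcs[[s]][[cond]], f)
      files <- c(files, f)
    }
  }
  pf <- file.path(dir, "partition.csv")
  write_partition(cohort$partition, pf)
  tf <- file.path(dir, "truth.json")
  jsonlite::write_json(list(most_perturbed_condition = cohort$truth$most_perturbed_condition,
                            most_perturbed_fn = cohort$truth$most_perturbed_fn,
                            effects = cohort$truth$effects,
                            seed = cohort$spec$seed),
                       tf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, pf, tf))
}
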