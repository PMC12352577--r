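#' Configuration of an end-to-end landscape run
#'
#' Collects every tunable of [run_pipeline()] in one validated object. The
#' cohort comes from exactly one of three sources, in priority order: an
#' in-memory `fc_cohort`, a directory of connectome files written in the
#' package's formats, or a fresh simulation from `spec` (or the default
#' [cohort_spec()] with `seed`).
#'
#' @param output_dir directory for all tables and the run summary.
#' @param cohort optional `fc_cohort`.
#' @param input_dir optional directory for [read_cohort()].
#' @param spec optional [cohort_spec()] to simulate from.
#' @param seed seed for the default simulation when no other source is
#'   given; all randomness in a run flows from this single value.
#' @param max_dim homological scope: diagrams for dimensions
#'   `0 .. max_dim - 1` (so `max_dim = 3` resolves H2). Default 2.
#' @param q Wasserstein order (> 1).
#' @param kl_bins,kl_pseudocount histogram KL estimator settings.
#' @param top_k pairs kept in the per-task ranking.
#' @param rest_label label of the rest condition.
#' @param verbose log stage progress and the parameter values in use.
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir, cohort = NULL, input_dir = NULL, spec = NULL,
                       seed = NULL, max_dim = 2, q = 2, kl_bins = 10,
                       kl_pseudocount = 1, top_k = 5, rest_label = "REST",
                       verbose = TRUE) {
  if (!(max_dim %in% 1:3)) stop("max_dim must be 1, 2 or 3")
  if (q <= 1) stop("q must be > 1")
  if (is.null(cohort) && is.null(input_dir) && is.null(spec) && is.null(seed)) {
    stop("provide a cohort, an input_dir, a spec, or a seed to simulate with")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir)
  }
  structure(list(output_dir = output_dir, cohort = cohort,
                 input_dir = input_dir, spec = spec, seed = seed,
                 max_dim = as.integer(max_dim), q = q, kl_bins = kl_bins,
                 kl_pseudocount = kl_pseudocount, top_k = top_k,
                 rest_label = rest_label, verbose = isTRUE(verbose)),
            class = "run_config")
}

.log <- function(cfg, ...) if (cfg$verbose) message(...)

.persistence_of <- function(fc, max_dim) {
  compute_persistence(build_flag_filtration(dissimilarity_matrix(fc), max_dim))
}

.tables_all_dims <- function(diagrams, max_dim, q) {
  lapply(setNames(0:(max_dim - 1), paste0("H", 0:(max_dim - 1))), function(p) {
    pairwise_distance_table(diagrams, dim = p, q = q)
  })
}

#' Run the five-level homological landscape analysis
#'
#' Executes, on one cohort: (1) the group-average macroscopic level
#' (condition-wise mean connectomes, their diagrams, pairwise distance
#' tables and profiles); (2) the consolidated level (the same on the
#' max-normalized functional-network super-graphs); (3) the mesoscopic
#' level (network-by-network tables of diagram distances between the
#' induced sub-connectomes of the group rest connectome); (4) the
#' individual consensus level (per-subject macroscopic tables, most
#' distinct pairs, vote counts); and (5) the individual all-to-rest level
#' (per-subject, per-network task-vs-rest distances, KL divergences between
#' network pairs per task, top-k rankings). All tables are written as CSV
#' under `output_dir` together with a JSON run summary naming inputs,
#' parameters, seed and per-level outputs; identical inputs and seed give
#' identical outputs. A failure in any stage aborts with the stage name.
#'
#' @param cfg a [run_config()].
#' @return the run summary, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("cfg must be a run_config")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- cfg$cohort
  if (is.null(cohort) && !is.null(cfg$input_dir)) cohort <- read_cohort(cfg$input_dir)
  if (is.null(cohort)) {
    spec <- cfg$spec %||% cohort_spec(seed = cfg$seed)
    .log(cfg, "simulating cohort (seed ", spec$seed, ")")
    cohort <- simulate_cohort(spec)
  }
  conditions <- names(cohort$fcs[[1]])
  subjects <- names(cohort$fcs)
  part <- cohort$partition
  fns <- part$class_names
  rest <- cfg$rest_label
  if (!rest %in% conditions) stop("rest condition '", rest, "' absent from cohort")
  .log(cfg, "cohort: ", length(subjects), " subjects, ", length(conditions),
       " conditions, ", length(part$sigma), " regions, ", part$k, " networks")
  .log(cfg, "parameters: max_dim=", cfg$max_dim, " q=", cfg$q,
       " kl_bins=", cfg$kl_bins, " kl_pseudocount=", cfg$kl_pseudocount,
       " top_k=", cfg$top_k,
       " (H0: Hausdorff on deaths; H1+: q-Wasserstein; ties: lexicographic)")
  summary <- list(parameters = list(max_dim = cfg$max_dim, q = cfg$q,
                                    kl_bins = cfg$kl_bins,
                                    kl_pseudocount = cfg$kl_pseudocount,
                                    top_k = cfg$top_k, rest = rest,
                                    seed = cohort$spec$seed %||% cfg$seed),
                  levels = list())
  out <- function(...) file.path(cfg$output_dir, paste0(...))
  stage <- function(name, expr) {
    .log(cfg, "level: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- level 1: group-average macroscopic ------------------------------------
  group_fcs <- stage("macroscopic", {
    gf <- lapply(setNames(conditions, conditions), function(cond) {
      group_average_fc(lapply(cohort$fcs, `[[`, cond))
    })
    dgms <- lapply(gf, .persistence_of, max_dim = cfg$max_dim)
    tabs <- .tables_all_dims(dgms, cfg$max_dim, cfg$q)
    files <- character(0)
    for (h in names(tabs)) {
      f <- out("macroscopic_distance_", h, ".csv")
      write_table_csv(tabs[[h]], f)
      prof <- condition_profiles(tabs[[h]])
      pf <- out("macroscopic_profile_", h, ".csv")
      write.csv(data.frame(condition = names(prof$means), mean = prof$means,
                           variance = prof$variances, row.names = NULL), pf,
                row.names = FALSE)
      files <- c(files, f, pf)
      summary$levels$macroscopic[[h]] <-
        list(most_distinct_pair = prof$most_distinct_pair,
             max_value = prof$max_value)
    }
    summary$levels$macroscopic$files <- files
    gf
  })

  # -- level 2: consolidated super-graph -------------------------------------
  stage("consolidated", {
    super <- lapply(group_fcs, function(fc) {
      consolidate_supergraph(fc, part)$normalized
    })
    sdim <- min(cfg$max_dim, 3L)
    dgms <- lapply(super, .persistence_of, max_dim = sdim)
    tabs <- .tables_all_dims(dgms, sdim, cfg$q)
    for (h in names(tabs)) {
      write_table_csv(tabs[[h]], out("consolidated_distance_", h, ".csv"))
      prof <- condition_profiles(tabs[[h]])
      summary$levels$consolidated[[h]] <-
        list(most_distinct_pair = prof$most_distinct_pair,
             max_value = prof$max_value,
             empty_diagrams = all(vapply(dgms, function(d) {
               p <- as.integer(sub("H", "", h))
               nrow(d[d$dimension == p & d$death > d$birth, ]) == 0
             }, TRUE)))
    }
    invisible(NULL)
  })

  # -- level 3: mesoscopic (rest, network-by-network) ------------------------
  stage("mesoscopic", {
    rest_fc <- group_fcs[[rest]]
    fn_dgms <- lapply(setNames(fns, fns), function(fn) {
      .persistence_of(induced_subnetwork(rest_fc, part, fn), cfg$max_dim)
    })
    tabs <- .tables_all_dims(fn_dgms, cfg$max_dim, cfg$q)
    for (h in names(tabs)) {
      write_table_csv(tabs[[h]], out("mesoscopic_rest_distance_", h, ".csv"))
      prof <- condition_profiles(tabs[[h]])
      summary$levels$mesoscopic[[h]] <-
        list(most_distinct_pair = prof$most_distinct_pair)
    }
    invisible(NULL)
  })

  # -- level 4: individual consensus -----------------------------------------
  subject_whole <- stage("consensus", {
    sw <- lapply(cohort$fcs, function(per_cond) {
      lapply(per_cond, .persistence_of, max_dim = cfg$max_dim)
    })
    for (p in 0:(cfg$max_dim - 1)) {
      tabs <- lapply(sw, function(dgms) {
        pairwise_distance_table(dgms, dim = p, q = cfg$q)
      })
      votes <- consensus_vote(tabs)
      write_table_csv(votes, out("consensus_H", p, ".csv"))
      idx <- which(votes == max(votes), arr.ind = TRUE)[1, ]
      summary$levels$consensus[[paste0("H", p)]] <-
        list(modal_pair = rownames(votes)[sort(idx)],
             modal_count = max(votes),
             n_subjects = attr(votes, "n_subjects"))
    }
    sw
  })

  # -- level 5: individual all-to-rest KL ------------------------------------
  stage("all_to_rest_kl", {
    sub_fn_dgms <- lapply(cohort$fcs, function(per_cond) {
      lapply(setNames(fns, fns), function(fn) {
        lapply(per_cond, function(fc) {
          .persistence_of(induced_subnetwork(fc, part, fn), cfg$max_dim)
        })
      })
    })
    tasks <- setdiff(conditions, rest)
    for (p in 0:(cfg$max_dim - 1)) {
      vecs <- lapply(setNames(fns, fns), function(fn) {
        lapply(setNames(tasks, tasks), function(task) {
          all_to_rest_distances(sub_fn_dgms, fn, task, dim = p, q = cfg$q,
                                rest = rest)
        })
      })
      long <- do.call(rbind, lapply(fns, function(fn) {
        do.call(rbind, lapply(tasks, function(task) {
          data.frame(fn = fn, task = task, subject = subjects,
                     distance = unname(vecs[[fn]][[task]]))
        }))
      }))
      write.csv(long, out("all_to_rest_distances_H", p, ".csv"), row.names = FALSE)
      for (task in tasks) {
        K <- matrix(0, part$k, part$k, dimnames = list(fns, fns))
        for (a in fns) for (b in fns) {
          if (a != b) {
            K[a, b] <- kl_divergence(vecs[[a]][[task]], vecs[[b]][[task]],
                                     bins = cfg$kl_bins,
                                     pseudocount = cfg$kl_pseudocount)
          }
        }
        write_table_csv(K, out("kl_H", p, "_", task, ".csv"))
        kk <- min(cfg$top_k, sum(row(K) != col(K)))
        top <- top_k_fn_pairs(K, kk)
        write.csv(top, out("top_pairs_H", p, "_", task, ".csv"), row.names = FALSE)
        summary$levels$all_to_rest_kl[[paste0("H", p)]][[task]] <-
          list(top_pair = c(top$fn_a[1], top$fn_b[1]), top_value = top$value[1])
      }
    }
    invisible(NULL)
  })

  summary$levels_completed <- c("macroscopic", "consolidated", "mesoscopic",
                                "consensus", "all_to_rest_kl")
  jsonlite::write_json(summary, file.path(cfg$output_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log(cfg, "done: 5 levels completed")
  invisible(summary)
}
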