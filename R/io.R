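#' Read / write connectome matrices as delimited text
#'
#' Square CSV with region ids as the first row and first column. On read,
#' asymmetry up to `1e-8` is symmetrized by averaging; larger asymmetry,
#' out-of-range weights or a non-unit diagonal are distinct errors (from
#' [fc_matrix()] validation).
#'
#' @param fc an [fc_matrix()].
#' @param path file path.
#' @return `read_fc` returns an [fc_matrix()]; `write_fc` returns the path
#'   invisibly.
#' @export
write_fc <- function(fc, path) {
  df <- as.data.frame(unclass(fc))
  write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric entries in connectome file ", path)
  colnames(M) <- colnames(df)
  fc_matrix(M, rownames(M))
}

#' Read / write a functional-network partition
#'
#' Two-column delimited text `(region_id, fn_label)`. When `region_ids` is
#' supplied the table is reconciled to that order by id; regions unknown to
#' either side are distinct, named errors.
#'
#' @param part an `fn_partition`.
#' @param path file path.
#' @param region_ids optional region order to reconcile against.
#' @return `read_partition` returns an `fn_partition`.
#' @export
write_partition <- function(part, path) {
  df <- data.frame(region_id = part$region_ids,
                   fn_label = part$class_names[part$sigma])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, region_ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("partition file must have two columns (region_id, fn_label)")
  ids <- as.character(df[[1]])
  labels <- as.character(df[[2]])
  if (!is.null(region_ids)) {
    unknown <- setdiff(ids, region_ids)
    if (length(unknown)) {
      stop("partition references unknown region(s): ", paste(unknown, collapse = ", "))
    }
    missing <- setdiff(region_ids, ids)
    if (length(missing)) {
      stop("partition missing region(s): ", paste(missing, collapse = ", "))
    }
    ord <- match(region_ids, ids)
    ids <- ids[ord]
    labels <- labels[ord]
  }
  fn_partition(labels, region_ids = ids)
}

#' Read / write persistence diagrams
#'
#' CSV with columns `(dim, birth, death, essential)`, one row per interval,
#' written at full precision so the round trip is lossless to 1e-12.
#' Intervals with `death < birth` are rejected on read.
#'
#' @param dgms a `persistence_diagrams` data frame.
#' @param path file path.
#' @return `read_diagram` returns a `persistence_diagrams` data frame.
#' @export
write_diagram <- function(dgms, path) {
  df <- data.frame(dim = dgms$dimension,
                   birth = sprintf("%.17g", dgms$birth),
                   death = sprintf("%.17g", dgms$death),
                   essential = as.integer(dgms$essential))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dim", "birth", "death", "essential")
  if (!all(need %in% names(df))) {
    stop("diagram file must have columns ", paste(need, collapse = ", "))
  }
  out <- data.frame(dimension = as.integer(df$dim),
                    birth = as.numeric(df$birth),
                    death = as.numeric(df$death),
                    essential = as.logical(as.integer(df$essential)))
  if (any(out$death < out$birth)) stop("invalid interval: death < birth")
  structure(out, class = c("persistence_diagrams", "data.frame"))
}

#' Load a cohort previously written with [write_cohort()]
#'
#' @param dir directory holding `<subject>_<condition>.csv` connectomes and
#'   `partition.csv`.
#' @return an `fc_cohort` (without a simulation spec; `truth` is read from
#'   `truth.json` when present).
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "^.+_.+\\.csv$")
  files <- setdiff(files, "partition.csv")
  if (length(files) == 0) stop("no connectome files found in ", dir)
  parts <- regmatches(files, regexec("^(.+)_([^_]+)\\.csv$", files))
  subjects <- unique(vapply(parts, `[`, "", 2))
  conditions <- unique(vapply(parts, `[`, "", 3))
  fcs <- lapply(subjects, function(s) {
    per <- lapply(conditions, function(cond) {
      f <- file.path(dir, paste0(s, "_", cond, ".csv"))
      if (!file.exists(f)) stop("missing connectome file ", f)
      read_fc(f)
    })
    names(per) <- conditions
    per
  })
  names(fcs) <- subjects
  ids <- rownames(fcs[[1]][[1]])
  part <- read_partition(file.path(dir, "partition.csv"), region_ids = ids)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(fcs = fcs, partition = part, truth = truth, spec = NULL),
            class = "fc_cohort")
}

#' Write a distance table (or any labelled matrix) as CSV
#' @param M labelled matrix.
#' @param path file path.
#' @export
write_table_csv <- function(M, path) {
  write.csv(as.data.frame(unclass(M)), path, row.names = TRUE)
  invisible(path)
}
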