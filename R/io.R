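#' Write a numeric matrix as full-precision CSV
#'
#' Values are printed with 17 significant digits so a write/read round trip
#' is lossless at double precision.
#'
#' @param M numeric matrix.
#' @param path output file path.
#' @export
write_matrix_csv <- function(M, path) {
  txt <- apply(M, 1L, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_csv()]
#'
#' Also accepts plain headerless CSV/TSV time-series files (and skips a
#' non-numeric header row if one is present).
#'
#' @param path file path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  M <- as.matrix(utils::read.table(path, sep = sep, header = has_header))
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  M
}

## Write a cohort's signals, manifest and ground-truth sidecar.
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- length(cohort$signals)
  ids <- sprintf("sub-%03d", seq_len(K))
  paths <- file.path(dir, paste0(ids, ".csv"))
  for (k in seq_len(K)) write_matrix_csv(cohort$signals[[k]], paths[k])
  manifest <- data.frame(subject_id = ids, label = cohort$labels,
                         path = basename(paths))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  truth <- list(
    n_rois = cohort$n_rois,
    n_per_class = cohort$n_per_class,
    n_time = cohort$n_time,
    seed = cohort$seed,
    backbone = as.data.frame(cohort$backbone),
    diff_edges = as.data.frame(cohort$diff_edges))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory (manifest plus per-subject CSVs)
#'
#' @param dir directory containing `manifest.csv` with columns
#'   `subject_id,label,path` and the referenced time-series files.
#' @return List with `signals` (list of matrices), `labels`, `subject_ids`.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("manifest.csv not found in ", dir)
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(manifest$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  signals <- lapply(manifest$path, function(p) {
    full <- if (file.exists(p)) p else file.path(dir, p)
    read_matrix_csv(full)
  })
  list(signals = as_cohort_list(signals),
       labels = as.integer(manifest$label),
       subject_ids = manifest$subject_id)
}

## Write estimated networks (one CSV per subject) plus a JSON sidecar with
## shapes, subject order, solver configuration and convergence diagnostics.
write_networks <- function(W, subject_ids, dir, config = NULL,
                           diagnostics = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- dim(W)[3]
  stopifnot(length(subject_ids) == K)
  for (k in seq_len(K)) {
    write_matrix_csv(W[, , k],
                     file.path(dir, paste0(subject_ids[k], "_network.csv")))
  }
  side <- list(n_rois = dim(W)[1], n_subjects = K, subject_order = subject_ids,
               config = config, diagnostics = diagnostics)
  jsonlite::write_json(side, file.path(dir, "networks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_networks <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "networks.json"),
                              simplifyVector = TRUE)
  ids <- side$subject_order
  N <- side$n_rois
  W <- array(0, dim = c(N, N, length(ids)))
  for (k in seq_along(ids)) {
    W[, , k] <- read_matrix_csv(file.path(dir, paste0(ids[k], "_network.csv")))
  }
  list(W = W, subject_ids = ids, sidecar = side)
}
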