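#' Write a synthetic cohort to disk
#'
#' Writes one wide CSV (one row per subject: covariates, biomarkers and
#' `<disease>_time` / `<disease>_event` outcome columns), a truth sidecar CSV
#' (true log-hazard coefficients and cluster label per disease) and a JSON
#' header recording the generation parameters and seed.
#'
#' @param cohort A `cohort_table`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- cbind(cohort$covariates, as.data.frame(cohort$biomarkers))
  for (d in colnames(cohort$time)) {
    wide[[paste0(d, "_time")]] <- cohort$time[, d]
    wide[[paste0(d, "_event")]] <- cohort$event[, d]
  }
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             truth = file.path(dir, "cohort_truth.csv"),
             header = file.path(dir, "cohort_header.json"))
  utils::write.csv(wide, paths["cohort"], row.names = FALSE)
  truth <- data.frame(disease = rownames(cohort$truth$beta),
                      cluster = cohort$truth$cluster,
                      cohort$truth$beta, check.names = FALSE)
  utils::write.csv(truth, paths["truth"], row.names = FALSE)
  spec <- cohort$params$spec
  jsonlite::write_json(
    list(seed = cohort$params$seed, baseline_rate = cohort$params$baseline_rate,
         horizon = cohort$params$horizon, spec = unclass(spec),
         sex_linked = cohort$truth$sex_linked),
    paths["header"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a synthetic cohort written by [write_cohort()]
#' @param dir Directory containing `cohort.csv` and `cohort_truth.csv`.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(dir) {
  wide <- utils::read.csv(file.path(dir, "cohort.csv"), check.names = FALSE)
  truth <- utils::read.csv(file.path(dir, "cohort_truth.csv"), check.names = FALSE)
  hdr <- jsonlite::read_json(file.path(dir, "cohort_header.json"),
                             simplifyVector = TRUE)
  cov_cols <- c("subject_id", "age", "sex", "deprivation", "bmi", "smoking", "sbp")
  bm_cols <- grep("^bm\\d+$", names(wide), value = TRUE)
  diseases <- truth$disease
  time <- as.matrix(wide[paste0(diseases, "_time")])
  event <- as.matrix(wide[paste0(diseases, "_event")])
  colnames(time) <- colnames(event) <- diseases
  beta <- as.matrix(truth[, bm_cols, drop = FALSE])
  rownames(beta) <- diseases
  spec <- do.call(archetype_spec, hdr$spec)
  structure(list(covariates = wide[cov_cols],
                 biomarkers = as.matrix(wide[bm_cols]),
                 time = time, event = event,
                 truth = list(beta = beta,
                              cluster = stats::setNames(truth$cluster, diseases),
                              sex_linked = hdr$sex_linked),
                 params = list(spec = spec, baseline_rate = hdr$baseline_rate,
                               horizon = hdr$horizon, seed = hdr$seed)),
            class = "cohort_table")
}

#' Write / read an EHR indicator table
#' @param ehr An `ehr_table` (0/1 matrix).
#' @param path CSV path.
#' @return `write_ehr` invisibly returns `path`; `read_ehr` returns the
#'   indicator matrix.
#' @export
write_ehr <- function(ehr, path) {
  utils::write.csv(as.data.frame(unclass(ehr)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ehr
#' @export
read_ehr <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write a hazard matrix as TSV
#'
#' Writes the diseases x covariates weighted hazard-ratio matrix and a
#' per-disease metrics table (case count, mean test C-index).
#'
#' @param hazards A `hazard_matrix`.
#' @param path TSV path for the HR matrix; metrics go to
#'   `<path base>_metrics.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_hazard_matrix <- function(hazards, path) {
  df <- data.frame(disease = rownames(hazards$hr), hazards$hr,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  mpath <- sub("\\.tsv$", "_metrics.tsv", path)
  meta <- hazards$metadata
  attr(meta, "fixed_covariates") <- NULL
  utils::write.table(meta, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(matrix = path, metrics = mpath))
}

#' Read a hazard matrix written by [write_hazard_matrix()]
#' @param path TSV path of the HR matrix.
#' @param fixed_covariates Names of the non-biomarker columns (default: the
#'   conventional age-spline/fixed set present in the file).
#' @return A `hazard_matrix` (metadata reloaded when the metrics file exists).
#' @export
read_hazard_matrix <- function(path, fixed_covariates = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  hr <- as.matrix(df[, -1, drop = FALSE])
  rownames(hr) <- df$disease
  if (is.null(fixed_covariates))
    fixed_covariates <- grep("^(age_bs\\d+|sex|deprivation|bmi|smoking|sbp)$",
                             colnames(hr), value = TRUE)
  mpath <- sub("\\.tsv$", "_metrics.tsv", path)
  metadata <- if (file.exists(mpath))
    utils::read.table(mpath, sep = "\t", header = TRUE) else NULL
  structure(list(hr = hr, metadata = metadata,
                 fixed_covariates = fixed_covariates,
                 removed_biomarkers = character(0),
                 excluded_diseases = character(0)),
            class = "hazard_matrix")
}

#' Write a similarity analysis to disk
#'
#' Correlation matrix TSV, permutation-null summary JSON, and the network
#' edge list TSV (`source  target  weight`).
#'
#' @param result A `similarity_result` from [similarity_analysis()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_similarity <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(correlation = file.path(dir, "correlation.tsv"),
             null = file.path(dir, "permutation_null.json"),
             edges = file.path(dir, "network_edges.tsv"))
  utils::write.table(
    data.frame(disease = rownames(result$correlation), result$correlation,
               check.names = FALSE),
    paths["correlation"], sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$null, paths["null"], auto_unbox = TRUE, digits = NA)
  utils::write.table(result$network$edges, paths["edges"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write a cluster assignment to disk
#'
#' Labels TSV (`disease  cluster  x  y`), the grid-search log TSV, and the
#' per-cluster mean-HR profile TSV.
#'
#' @param assignment A `cluster_assignment`.
#' @param hazards Hazard matrix used for the per-cluster profile.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_clusters <- function(assignment, hazards, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = file.path(dir, "cluster_labels.tsv"),
             grid = file.path(dir, "grid_search_log.tsv"),
             profile = file.path(dir, "cluster_profiles.tsv"))
  utils::write.table(
    data.frame(disease = names(assignment$labels),
               cluster = assignment$labels,
               x = assignment$embedding[, 1], y = assignment$embedding[, 2]),
    paths["labels"], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(assignment$grid_log, paths["grid"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  prof <- cluster_profile(assignment$labels, hazards)
  utils::write.table(data.frame(cluster = rownames(prof), prof,
                                check.names = FALSE),
                     paths["profile"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Write / read a comorbidity association matrix
#' @param assoc An `association_matrix`.
#' @param path TSV path.
#' @return `write_association` invisibly returns `path`; `read_association`
#'   returns an `association_matrix`.
#' @export
write_association <- function(assoc, path) {
  co <- .assoc_coef(assoc)
  utils::write.table(data.frame(disease = rownames(co), co, check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  co <- as.matrix(df[, -1, drop = FALSE])
  rownames(co) <- df$disease
  structure(list(coef = co, min_cases = NA_integer_, skipped = character(0)),
            class = "association_matrix")
}

#' Write a validation report to disk
#'
#' TMR curve TSV (`tau  tmr  n_pairs`) and the report JSON (actual AUC,
#' baseline mean/sd and replicates, validation score, seed).
#'
#' @param report A `validation_report`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_validation <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(curve = file.path(dir, "tmr_curve.tsv"),
             report = file.path(dir, "validation_report.json"))
  utils::write.table(report$curve, paths["curve"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(actual_auc = report$actual_auc,
         baseline_auc = report$baseline$mean,
         baseline_sd = report$baseline$sd,
         baseline_aucs = report$baseline$aucs,
         validation_score = report$validation_score,
         n_replicates = report$n_replicates, seed = report$seed),
    paths["report"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
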