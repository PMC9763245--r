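# Resolve labels from a cluster_assignment or a named vector.
.val_labels <- function(labels) {
  if (inherits(labels, "cluster_assignment")) labels$labels else labels
}

# Unordered pair table: max of the two directed association coefficients,
# cluster match indicator. Universe = diseases present in both inputs; noise
# (label 0) excluded by default, or kept as automatic non-matches.
.pair_table <- function(assoc, labels, include_noise = FALSE) {
  co <- .assoc_coef(assoc)
  labels <- .val_labels(labels)
  shared <- intersect(rownames(co), names(labels))
  if (!length(shared)) stop("association matrix and labels share no disease")
  l <- labels[shared]
  if (!include_noise) {
    shared <- shared[l != 0L]
    l <- l[l != 0L]
  }
  if (length(shared) < 2)
    return(data.frame(assoc = numeric(0), match = logical(0)))
  co <- co[shared, shared]
  ut <- which(upper.tri(co), arr.ind = TRUE)
  pair_assoc <- pmax(co[ut], co[ut[, c(2, 1), drop = FALSE]], na.rm = TRUE)
  match <- l[ut[, 1]] == l[ut[, 2]] & l[ut[, 1]] != 0L
  data.frame(assoc = pair_assoc, match = match)
}

#' True match rate at one association threshold
#'
#' Among unordered disease pairs whose comorbidity association (max of the
#' two directed coefficients) exceeds `tau`, the fraction assigned to the same
#' cluster. Noise-labeled diseases are excluded from the pair universe by
#' default; with `include_noise = TRUE` they are kept and count as automatic
#' non-matches.
#'
#' @param assoc An `association_matrix` (or plain directed matrix).
#' @param labels A `cluster_assignment` or named integer label vector
#'   (0 = noise).
#' @param tau Association cutoff (pairs must exceed it strictly).
#' @param include_noise Keep noise-labeled diseases as non-matches.
#' @return List with `tmr` (`NA` when no pair exceeds `tau`) and `n_pairs`.
#' @export
tmr_at <- function(assoc, labels, tau, include_noise = FALSE) {
  pt <- .pair_table(assoc, labels, include_noise)
  above <- pt$assoc > tau & !is.na(pt$assoc)
  n <- sum(above)
  list(tmr = if (n > 0) mean(pt$match[above]) else NA_real_, n_pairs = n)
}

#' True-match-rate curve over an association-threshold grid
#'
#' Evaluates [tmr_at()] on a descending threshold grid. The default grid is
#' the sorted unique positive association values, so the TMR step function is
#' evaluated exactly at its jump points. Thresholds with no pair above them
#' yield explicit gaps (`NA`).
#'
#' @inheritParams tmr_at
#' @param tau_grid Threshold grid; sorted into strictly decreasing order.
#' @return Object of class `tmr_curve`: data.frame with `tau`, `tmr`,
#'   `n_pairs`.
#' @export
tmr_curve <- function(assoc, labels, tau_grid = NULL, include_noise = FALSE) {
  pt <- .pair_table(assoc, labels, include_noise)
  if (is.null(tau_grid)) {
    tau_grid <- sort(unique(pt$assoc[pt$assoc > 0 & !is.na(pt$assoc)]),
                     decreasing = TRUE)
    if (!length(tau_grid))
      stop("no positive association value to build the default threshold grid")
  }
  tau_grid <- sort(unique(tau_grid), decreasing = TRUE)
  rows <- lapply(tau_grid, function(tau) {
    above <- pt$assoc > tau & !is.na(pt$assoc)
    n <- sum(above)
    data.frame(tau = tau,
               tmr = if (n > 0) mean(pt$match[above]) else NA_real_,
               n_pairs = n)
  })
  structure(do.call(rbind, rows), class = c("tmr_curve", "data.frame"))
}

#' Trapezoidal area under a TMR curve
#'
#' Integrates the true match rate over the association threshold with the
#' trapezoidal rule across the defined points (gaps are bridged by omission:
#' undefined thresholds are dropped and the trapezoid spans the neighboring
#' defined points). The area is in tau x TMR units, not normalized by the
#' threshold range.
#'
#' @param curve A `tmr_curve` (or data.frame with `tau` and `tmr`).
#' @return The area (numeric scalar).
#' @export
auc_trapezoid <- function(curve) {
  ok <- !is.na(curve$tmr)
  tau <- curve$tau[ok]; tmr <- curve$tmr[ok]
  if (length(tau) < 2) stop("need at least 2 defined TMR points")
  o <- order(tau)
  tau <- tau[o]; tmr <- tmr[o]
  sum(diff(tau) * (utils::head(tmr, -1) + utils::tail(tmr, -1)) / 2)
}

#' Permuted-matrix random baseline for the TMR AUC
#'
#' Per replicate: permute the biomarker log-HR submatrix (within-row scheme
#' by default, matching the similarity-map null), re-embed and re-cluster
#' with the already chosen UMAP/DBSCAN parameters (the grid search is not
#' re-run), recompute the TMR curve against the same association matrix and
#' threshold grid, and record its AUC. Replicates whose curve has fewer than
#' two defined points are resampled (with a message); if every attempt fails
#' the call errors.
#'
#' @param submatrix Diseases x biomarkers log-HR matrix (pre-exclusion
#'   output of [biomarker_submatrix()]).
#' @param assoc The association matrix the actual AUC was computed against.
#' @param params List with `n_neighbors`, `min_dist`, `eps`, `min_samples`
#'   (e.g. `chosen_params` of a [grid_search_clustering()] result).
#' @param tau_grid Threshold grid shared with the actual curve.
#' @param n_replicates Number of permutation replicates (>= 1).
#' @param seed Integer seed.
#' @param scheme Permutation scheme, `"within_row"` or `"global"`.
#' @param include_noise Passed to [tmr_curve()].
#' @return List with `aucs`, `mean`, `sd`, `n_replicates`, `n_resampled`.
#' @export
random_baseline <- function(submatrix, assoc, params, tau_grid = NULL,
                            n_replicates = 20L, seed = 1L,
                            scheme = c("within_row", "global"),
                            include_noise = FALSE) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  scheme <- match.arg(scheme)
  aucs <- numeric(n_replicates)
  n_resampled <- 0L
  attempt <- 0L
  max_attempts <- n_replicates * 10L
  b <- 1L
  while (b <= n_replicates) {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("random baseline failed: every permutation replicate yielded an ",
           "undefined TMR curve")
    rep_seed <- seed + attempt
    set.seed(rep_seed)
    perm <- .permute_hazards(submatrix, scheme)
    emb <- embed_2d(perm, params$n_neighbors, params$min_dist, seed = rep_seed)
    labels <- density_cluster(emb, params$eps, params$min_samples)
    auc <- tryCatch(
      auc_trapezoid(tmr_curve(assoc, labels, tau_grid, include_noise)),
      error = function(e) NA_real_)
    if (is.na(auc)) {
      n_resampled <- n_resampled + 1L
      message("resampling baseline replicate ", b,
              " (undefined TMR curve at attempt ", attempt, ")")
      next
    }
    aucs[b] <- auc
    b <- b + 1L
  }
  list(aucs = aucs, mean = mean(aucs), sd = stats::sd(aucs),
       n_replicates = n_replicates, n_resampled = n_resampled)
}

#' Cluster validation score
#'
#' Ratio of the actual TMR-curve AUC to the mean AUC under clusterings of
#' permuted hazard matrices; values above 1 indicate that the biomarker
#' clusters are enriched for comorbid disease pairs beyond chance.
#'
#' @param actual_auc AUC of the observed cluster labels.
#' @param baseline_auc Mean permuted-matrix AUC (> 0).
#' @return The ratio.
#' @export
validation_score <- function(actual_auc, baseline_auc) {
  if (baseline_auc <= 0) stop("baseline AUC must be > 0 for a defined score")
  actual_auc / baseline_auc
}

#' End-to-end cluster validation report
#'
#' Computes the actual TMR curve and AUC for a cluster assignment against a
#' comorbidity association matrix, the permuted-matrix baseline AUC
#' distribution, and the validation score.
#'
#' @param submatrix Diseases x biomarkers log-HR matrix used for clustering.
#' @param assoc An `association_matrix`.
#' @param assignment A [grid_search_clustering()] result (its labels and
#'   chosen parameters are reused for the baseline replicates).
#' @param n_replicates Number of baseline permutation replicates.
#' @param seed Integer seed.
#' @param tau_grid Optional shared threshold grid (default: unique positive
#'   association values of the actual pair table).
#' @param include_noise Passed to the TMR computations.
#' @return Object of class `validation_report`: `curve`, `actual_auc`,
#'   `baseline` (the [random_baseline()] result), `validation_score`,
#'   `n_replicates`, `seed`.
#' @export
validate_clusters <- function(submatrix, assoc, assignment,
                              n_replicates = 20L, seed = 1L, tau_grid = NULL,
                              include_noise = FALSE) {
  curve <- tmr_curve(assoc, assignment, tau_grid, include_noise)
  actual <- auc_trapezoid(curve)
  baseline <- random_baseline(submatrix, assoc, assignment$chosen_params,
                              curve$tau, n_replicates, seed,
                              include_noise = include_noise)
  structure(list(curve = curve, actual_auc = actual, baseline = baseline,
                 validation_score = validation_score(actual, baseline$mean),
                 n_replicates = n_replicates, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Cluster validation: actual AUC", signif(x$actual_auc, 4),
      "vs baseline", signif(x$baseline$mean, 4), "+/-",
      signif(x$baseline$sd, 3), "->", "validation score",
      signif(x$validation_score, 4), "\n")
  invisible(x)
}
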