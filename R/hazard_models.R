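#' Drop highly correlated biomarkers
#'
#' Greedy pruning in column order: a column is removed if its absolute Pearson
#' correlation with any previously retained column is at or above `threshold`.
#' Column order is the documented, deterministic tie-break. Constant columns
#' (zero variance) are removed with a warning since their correlation is
#' undefined.
#'
#' @param panel Numeric matrix with named columns.
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return List with `retained` and `removed` column-name vectors
#'   (their union is the input column set).
#' @export
drop_correlated_biomarkers <- function(panel, threshold = 0.7) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cols <- colnames(panel)
  if (is.null(cols)) cols <- as.character(seq_len(ncol(panel)))
  sds <- apply(panel, 2L, stats::sd)
  constant <- cols[sds == 0]
  if (length(constant))
    warning("removing constant column(s): ", paste(constant, collapse = ", "))
  retained <- character(0)
  removed <- constant
  for (j in setdiff(cols, constant)) {
    if (length(retained) &&
        any(abs(stats::cor(panel[, j], panel[, retained, drop = FALSE])) >= threshold)) {
      removed <- c(removed, j)
    } else {
      retained <- c(retained, j)
    }
  }
  list(retained = retained, removed = removed)
}

#' Standardize a biomarker panel
#'
#' Mean-centers and scales every column to unit sample standard deviation,
#' returning the transform parameters so the same transform (fitted on a
#' training split) can be applied to a test split and inverted.
#'
#' @param panel Numeric matrix; every column must have positive variance.
#' @return The standardized matrix with attributes `center` and `scale`
#'   (named per column).
#' @seealso [apply_zscale()], [invert_zscale()]
#' @export
zscale <- function(panel) {
  ctr <- colMeans(panel)
  scl <- apply(panel, 2L, stats::sd)
  bad <- colnames(panel)[scl == 0]
  if (length(bad))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  out <- sweep(sweep(panel, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Apply a previously estimated z-scaling transform
#' @param panel Numeric matrix with the same columns as the training panel.
#' @param scaled A matrix returned by [zscale()] (source of `center`/`scale`),
#'   or a list with `center` and `scale` vectors.
#' @return Standardized matrix.
#' @export
apply_zscale <- function(panel, scaled) {
  ctr <- attr(scaled, "center") %||% scaled$center
  scl <- attr(scaled, "scale") %||% scaled$scale
  sweep(sweep(panel, 2L, ctr[colnames(panel)], "-"), 2L, scl[colnames(panel)], "/")
}

#' Invert a z-scaling transform
#' @inheritParams apply_zscale
#' @return Matrix on the original scale.
#' @export
invert_zscale <- function(panel, scaled) {
  ctr <- attr(scaled, "center") %||% scaled$center
  scl <- attr(scaled, "scale") %||% scaled$scale
  sweep(sweep(panel, 2L, scl[colnames(panel)], "*"), 2L, ctr[colnames(panel)], "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Harrell's concordance index
#'
#' Fraction of comparable subject pairs in which the subject with the higher
#' risk score experiences the event earlier. A pair is comparable when the
#' earlier time is an observed event (a subject censored at the same time as
#' an event is taken to survive longer); pairs of events at identical times
#' are not comparable. Ties in risk score count 0.5.
#'
#' @param risk_scores Numeric vector of predicted risks (higher = riskier).
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return Concordance in [0, 1]. Errors if there is no comparable pair
#'   (rather than returning 0.5).
#' @export
concordance_index <- function(risk_scores, times, events) {
  n <- length(risk_scores)
  if (length(times) != n || length(events) != n)
    stop("risk_scores, times and events must have equal length")
  if (any(times <= 0)) stop("times must be strictly positive")
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    cmp <- times > times[i] | (times == times[i] & events == 0)
    cmp[i] <- FALSE
    if (!any(cmp)) next
    r <- risk_scores[cmp]
    num <- num + sum(risk_scores[i] > r) + 0.5 * sum(risk_scores[i] == r)
    den <- den + length(r)
  }
  if (den == 0) stop("no comparable pairs: concordance is undefined")
  num / den
}

#' C-index ensemble weights
#'
#' Normalizes a vector of held-out concordance indices into ensemble weights
#' `W_i = c_i / sum_j c_j`, which sum to 1 exactly.
#'
#' @param cindex Vector of concordance indices in (0, 1].
#' @return Weight vector of the same length.
#' @export
ensemble_weights <- function(cindex) {
  if (any(cindex <= 0)) stop("C-indices must be positive to form weights")
  cindex / sum(cindex)
}

#' Design for the per-disease Cox model ensemble
#'
#' @param penalty_grid Strictly increasing, strictly positive L2 penalties.
#'   Default: 20 evenly spaced values in [0.01, 0.2].
#' @param split_fraction Training fraction of the 70/30-style split, in (0,1).
#' @param age_spline_degree Degree of the B-spline age basis.
#' @param age_knot_probs Quantile probabilities of the interior knots,
#'   estimated on the training split's ages (default: quintiles).
#' @param min_split_events Minimum number of events required in each split.
#' @param seed Integer seed governing the train/test split.
#' @return Object of class `model_design`.
#' @export
model_design <- function(penalty_grid = seq(0.01, 0.2, length.out = 20),
                         split_fraction = 0.7, age_spline_degree = 4L,
                         age_knot_probs = c(0.2, 0.4, 0.6, 0.8),
                         min_split_events = 10L, seed = 1L) {
  if (any(penalty_grid <= 0) || is.unsorted(penalty_grid, strictly = TRUE))
    stop("penalty_grid must be strictly positive and strictly increasing")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  structure(list(penalty_grid = penalty_grid, split_fraction = split_fraction,
                 age_spline_degree = as.integer(age_spline_degree),
                 age_knot_probs = age_knot_probs,
                 min_split_events = as.integer(min_split_events),
                 seed = as.integer(seed)),
            class = "model_design")
}

# Build the Cox design matrix: degree-d B-spline age basis (knots from the
# training ages), the remaining fixed covariates as-is, and train-z-scaled
# biomarkers. Returns train/test matrices plus the fixed-covariate column set.
.cox_design_matrices <- function(covariates, biomarkers, train, design) {
  age_tr <- covariates$age[train]
  # interior knots from the training ages; boundary knots span the whole
  # cohort so the test split never falls outside the basis support
  basis <- splines::bs(age_tr, degree = design$age_spline_degree,
                       knots = stats::quantile(age_tr, design$age_knot_probs),
                       Boundary.knots = range(covariates$age))
  age_cols <- sprintf("age_bs%d", seq_len(ncol(basis)))
  fixed <- c("sex", "deprivation", "bmi", "smoking", "sbp")
  fx <- as.matrix(covariates[, fixed])
  ztr <- zscale(biomarkers[train, , drop = FALSE])
  zte <- apply_zscale(biomarkers[!train, , drop = FALSE], ztr)
  xtr <- cbind(basis, fx[train, , drop = FALSE], ztr)
  xte <- cbind(stats::predict(basis, covariates$age[!train]),
               fx[!train, , drop = FALSE], zte)
  colnames(xtr) <- colnames(xte) <-
    c(age_cols, fixed, colnames(biomarkers))
  list(train = xtr, test = xte, fixed_covariates = c(age_cols, fixed))
}

#' Fit the C-index-weighted ensemble of L2-penalized Cox models for one disease
#'
#' Splits the cohort into training/test sets (stratified by event status so
#' rare diseases keep events in both splits), fits one ridge-penalized Cox
#' proportional-hazards model per penalty in the grid on the training split,
#' scores each model by Harrell's C-index on the held-out split, and averages
#' the log-hazard coefficients across penalties with weights proportional to
#' the C-indices. The weighted hazard ratio per covariate is
#' `exp(sum_i W_i beta_i)` — weighting happens on the log scale and is
#' exponentiated once, so hazard ratios stay positive.
#'
#' @param cohort A `cohort_table` (see [simulate_cohort()]) or a list with
#'   `covariates`, `biomarkers`, `time`, `event`.
#' @param disease Disease identifier (a column of `cohort$time`).
#' @param design A [model_design()].
#' @return Object of class `ensemble_fit` with `per_penalty_betas`
#'   (penalties x covariates), `per_penalty_cindex`, `weights`, `weighted_hr`,
#'   `test_cindex_summary` (the mean), `n_cases` and `penalty_grid`.
#' @export
fit_cox_ensemble <- function(cohort, disease, design = model_design()) {
  time <- cohort$time[, disease]
  event <- cohort$event[, disease]
  set.seed(design$seed)
  n <- length(time)
  train <- logical(n)
  for (grp in list(which(event == 1), which(event == 0))) {
    k <- round(design$split_fraction * length(grp))
    train[sample(grp, k)] <- TRUE
  }
  if (sum(event[train]) < design$min_split_events ||
      sum(event[!train]) < design$min_split_events)
    stop("disease ", disease, " has fewer than ", design$min_split_events,
         " events in a split")
  dm <- .cox_design_matrices(cohort$covariates, cohort$biomarkers, train, design)
  y <- survival::Surv(time[train], event[train])
  lambdas <- sort(design$penalty_grid, decreasing = TRUE)
  fit <- glmnet::glmnet(dm$train, y, family = "cox", alpha = 0,
                        lambda = lambdas, standardize = FALSE, thresh = 1e-10)
  beta <- as.matrix(fit$beta)            # covariates x fitted penalties
  kept <- match(fit$lambda, lambdas)
  if (length(kept) < length(lambdas))
    warning("dropped ", length(lambdas) - length(kept),
            " penalty value(s) that failed to converge for disease ", disease)
  if (ncol(beta) == 0) stop("all penalties failed for disease ", disease)
  pen <- fit$lambda
  risk <- dm$test %*% beta
  cindex <- apply(risk, 2L, concordance_index,
                  times = time[!train], events = event[!train])
  w <- ensemble_weights(cindex)
  wbeta <- drop(beta %*% w)
  structure(list(per_penalty_betas = t(beta),
                 per_penalty_cindex = stats::setNames(cindex, pen),
                 weights = stats::setNames(w, pen),
                 weighted_hr = exp(wbeta),
                 test_cindex_summary = mean(cindex),
                 n_cases = sum(event),
                 penalty_grid = pen,
                 fixed_covariates = dm$fixed_covariates,
                 disease = disease),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("Cox ensemble for", x$disease, "-", x$n_cases, "cases,",
      length(x$penalty_grid), "penalties, mean test C-index",
      round(x$test_cindex_summary, 3), "\n")
  invisible(x)
}

#' Assemble the weighted hazard-ratio matrix across diseases
#'
#' Prunes correlated biomarkers once on the full panel, then fits the Cox
#' ensemble for every disease whose case count meets the incidence threshold
#' and stacks the weighted hazard ratios into the diseases x covariates atlas
#' matrix.
#'
#' @param cohort A `cohort_table`.
#' @param design A [model_design()].
#' @param incidence_threshold Minimum total case count for a disease to be
#'   modeled.
#' @param prune_threshold Absolute-correlation cutoff for biomarker pruning.
#' @return Object of class `hazard_matrix`: list with `hr` (diseases x
#'   covariates matrix of weighted hazard ratios), `metadata` (per-disease
#'   case count and mean test C-index), `fixed_covariates` (non-biomarker
#'   column names), `removed_biomarkers` and `excluded_diseases`.
#' @export
build_hazard_matrix <- function(cohort, design = model_design(),
                                incidence_threshold = 100L,
                                prune_threshold = 0.7) {
  cases <- colSums(cohort$event)
  keep <- names(cases)[cases >= incidence_threshold]
  if (!length(keep))
    stop("no disease reaches the incidence threshold of ", incidence_threshold)
  pruned <- drop_correlated_biomarkers(cohort$biomarkers, prune_threshold)
  bm <- cohort$biomarkers[, pruned$retained, drop = FALSE]
  cohort2 <- cohort
  cohort2$biomarkers <- bm
  fits <- lapply(keep, function(d) fit_cox_ensemble(cohort2, d, design))
  hr <- do.call(rbind, lapply(fits, function(f) f$weighted_hr))
  rownames(hr) <- keep
  metadata <- data.frame(
    disease = keep,
    n_cases = cases[keep],
    mean_cindex = vapply(fits, function(f) f$test_cindex_summary, numeric(1)),
    row.names = NULL
  )
  structure(list(hr = hr, metadata = metadata,
                 fixed_covariates = fits[[1]]$fixed_covariates,
                 removed_biomarkers = pruned$removed,
                 excluded_diseases = setdiff(names(cases), keep)),
            class = "hazard_matrix")
}

#' @export
print.hazard_matrix <- function(x, ...) {
  cat("Hazard matrix:", nrow(x$hr), "diseases x", ncol(x$hr), "covariates (",
      length(x$fixed_covariates), "fixed ), mean C-index",
      round(mean(x$metadata$mean_cindex), 3), "\n")
  invisible(x)
}
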