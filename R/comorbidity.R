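#' Lasso-logistic comorbidity model for one disease
#'
#' L1-penalized logistic regression of a target disease indicator on all
#' other disease indicators (plus an optional covariate table, with age
#' entering through the same degree-4 B-spline basis as the survival models).
#' The penalty is chosen by K-fold cross-validated deviance; coefficients are
#' taken at `lambda.min` so that weak associations survive for downstream
#' threshold curves. Covariate coefficients are estimated but excluded from
#' the returned association vector.
#'
#' @param ehr An `ehr_table` (0/1 matrix, columns = diseases).
#' @param target Disease identifier (column of `ehr`).
#' @param covariates Optional data.frame of per-subject covariates
#'   (columns among `age`, `sex`, `deprivation`, `bmi`, `smoking`).
#' @param cv_folds Number of CV folds (>= 2).
#' @param seed Integer seed (fold assignment).
#' @return Named numeric vector of penalized log-odds coefficients over the
#'   other diseases (zeros mean "eliminated by the penalty"), with the fitted
#'   covariate coefficients in attribute `covariate_coefs`.
#' @export
fit_comorbidity_model <- function(ehr, target, covariates = NULL,
                                  cv_folds = 5L, seed = 1L) {
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  y <- ehr[, target]
  if (sum(y) == 0 || sum(y) == nrow(ehr))
    stop("target ", target, " has zero cases or zero controls")
  others <- setdiff(colnames(ehr), target)
  x <- ehr[, others, drop = FALSE]
  cov_cols <- character(0)
  if (!is.null(covariates)) {
    cm <- NULL
    if ("age" %in% names(covariates)) {
      basis <- splines::bs(covariates$age, degree = 4L,
                           knots = stats::quantile(covariates$age,
                                                   c(0.2, 0.4, 0.6, 0.8)))
      colnames(basis) <- sprintf("age_bs%d", seq_len(ncol(basis)))
      cm <- basis
    }
    rest <- intersect(c("sex", "deprivation", "bmi", "smoking"),
                      names(covariates))
    if (length(rest)) cm <- cbind(cm, as.matrix(covariates[, rest, drop = FALSE]))
    cov_cols <- colnames(cm)
    x <- cbind(x, cm)
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), nrow(x)))
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                           foldid = foldid, standardize = FALSE)
  coefs <- drop(as.matrix(stats::coef(fit, s = "lambda.min")))[-1]
  out <- coefs[others]
  attr(out, "covariate_coefs") <- coefs[cov_cols]
  out
}

#' Disease-disease comorbidity association matrix
#'
#' Fits one lasso-logistic co-occurrence model per qualifying disease and
#' assembles the directed association matrix: entry (k, i) is the penalized
#' log-odds coefficient of disease i in the model for disease k. The matrix
#' is not forced symmetric; the diagonal is `NA` (a disease never predicts
#' itself).
#'
#' @inheritParams fit_comorbidity_model
#' @param min_cases Minimum case count for a disease to get its own model.
#' @return Object of class `association_matrix`: list with `coef` (m x m
#'   directed matrix, NA diagonal), `min_cases`, `skipped` (diseases below
#'   the case threshold).
#' @export
association_matrix <- function(ehr, covariates = NULL, cv_folds = 5L,
                               seed = 1L, min_cases = 50L) {
  cases <- colSums(ehr)
  qualify <- colnames(ehr)[cases >= min_cases & cases <= nrow(ehr) - min_cases]
  if (length(qualify) < 2)
    stop("fewer than 2 diseases reach the case threshold of ", min_cases)
  m <- ncol(ehr)
  coef <- matrix(NA_real_, m, m, dimnames = list(colnames(ehr), colnames(ehr)))
  for (k in qualify) {
    b <- fit_comorbidity_model(ehr, k, covariates, cv_folds, seed)
    coef[k, names(b)] <- b
  }
  diag(coef) <- NA_real_
  structure(list(coef = coef, min_cases = min_cases,
                 skipped = setdiff(colnames(ehr), qualify)),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  nz <- sum(x$coef != 0, na.rm = TRUE)
  cat("Comorbidity associations:", nrow(x$coef), "diseases,", nz,
      "nonzero directed coefficients\n")
  invisible(x)
}

.assoc_coef <- function(assoc) {
  if (inherits(assoc, "association_matrix")) assoc$coef else assoc
}

#' Cross-cohort concordance of comorbidity associations
#'
#' Aligns the directed disease pairs shared by two association matrices and
#' reports the Pearson correlation of the paired coefficients (exactly 1 for
#' identical matrices), its square
#' (`R2 = r^2` for this simple pairing), and the concordant/discordant pair
#' counts at an association threshold (a directed pair is concordant when
#' both cohorts are on the same side of the threshold).
#'
#' @param a,b `association_matrix` objects (or plain matrices).
#' @param assoc_threshold Association cutoff used for the concordance counts.
#' @return Object of class `concordance_report`: `r`, `r_squared`, `n_pairs`,
#'   `n_concordant`, `n_discordant`, `discordant` (data.frame of directed
#'   pairs where exactly one cohort exceeds the threshold), `pairs`
#'   (data.frame of all shared directed pairs with both coefficients).
#' @export
cross_cohort_concordance <- function(a, b, assoc_threshold = 0.1) {
  ca <- .assoc_coef(a); cb <- .assoc_coef(b)
  shared <- intersect(rownames(ca), rownames(cb))
  if (length(shared) < 2) stop("no shared diseases between cohorts")
  ca <- ca[shared, shared]; cb <- cb[shared, shared]
  ok <- !is.na(ca) & !is.na(cb)
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("fewer than 3 shared directed pairs")
  va <- ca[ok]; vb <- cb[ok]
  # identical coefficient vectors are guaranteed r = 1 exactly (floating-point
  # summation in cor() would otherwise land an ulp away from 1)
  r <- if (identical(va, vb)) 1 else stats::cor(va, vb)
  above_a <- va >= assoc_threshold; above_b <- vb >= assoc_threshold
  disc <- above_a != above_b
  structure(list(
    r = r, r_squared = r^2, n_pairs = length(va),
    n_concordant = sum(!disc), n_discordant = sum(disc),
    discordant = data.frame(target = shared[idx[disc, 1]],
                            predictor = shared[idx[disc, 2]],
                            coef_a = va[disc], coef_b = vb[disc]),
    pairs = data.frame(target = shared[idx[, 1]],
                       predictor = shared[idx[, 2]],
                       coef_a = va, coef_b = vb),
    assoc_threshold = assoc_threshold
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cross-cohort concordance over", x$n_pairs, "directed pairs: r =",
      round(x$r, 3), ", R^2 =", round(x$r_squared, 3), ",", x$n_discordant,
      "discordant at threshold", x$assoc_threshold, "\n")
  invisible(x)
}

#' Comorbidity among biochemically similar disease pairs
#'
#' Among unordered disease pairs whose biomarker-profile correlation reaches
#' `corr_threshold`, counts the fraction that are also comorbid — a pair is
#' comorbid when either directed association coefficient reaches
#' `assoc_threshold` (default 0.1, i.e. odds ratio > 1.1).
#'
#' @param correlation Disease x disease correlation matrix.
#' @param assoc An `association_matrix` (or plain directed matrix).
#' @param corr_threshold Similarity cutoff (default 0.5).
#' @param assoc_threshold Association cutoff (default 0.1).
#' @return List with `fraction` (`NA` when no pair passes `corr_threshold`,
#'   flagged by `undefined`), `n_similar`, `concordant` and `discordant`
#'   pair data.frames (similar+comorbid vs similar-but-not-comorbid).
#' @export
comorbid_given_similar <- function(correlation, assoc, corr_threshold = 0.5,
                                   assoc_threshold = 0.1) {
  co <- .assoc_coef(assoc)
  shared <- intersect(rownames(correlation), rownames(co))
  if (length(shared) < 2) stop("matrices share fewer than 2 diseases")
  cc <- correlation[shared, shared]
  co <- co[shared, shared]
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  sim <- cc[ut] >= corr_threshold
  if (!any(sim))
    return(list(fraction = NA_real_, undefined = TRUE, n_similar = 0L,
                concordant = .empty_pairs(), discordant = .empty_pairs()))
  idx <- ut[sim, , drop = FALSE]
  pair_assoc <- pmax(co[idx], co[idx[, c(2, 1), drop = FALSE]], na.rm = TRUE)
  comorbid <- !is.na(pair_assoc) & pair_assoc >= assoc_threshold
  mk <- function(sel) data.frame(disease_a = shared[idx[sel, 1]],
                                 disease_b = shared[idx[sel, 2]],
                                 correlation = cc[idx][sel],
                                 association = pair_assoc[sel])
  list(fraction = mean(comorbid), undefined = FALSE, n_similar = sum(sim),
       concordant = mk(comorbid), discordant = mk(!comorbid))
}

.empty_pairs <- function() {
  data.frame(disease_a = character(0), disease_b = character(0),
             correlation = numeric(0), association = numeric(0))
}
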