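#' Specification of latent risk-profile archetypes
#'
#' An archetype is a latent log-hazard profile shared by a group of diseases.
#' Diseases belonging to the same archetype have (up to perturbation) the same
#' per-SD biomarker effects on their hazard, so true disease clusters exist by
#' construction and downstream recovery can be scored against them.
#'
#' @param n_archetypes Number of latent risk-profile groups (>= 1).
#' @param n_diseases Number of diseases (>= `n_archetypes`). Diseases are
#'   assigned to archetypes as evenly as possible, in order.
#' @param n_biomarkers Number of biomarkers in the panel.
#' @param effect_scale Standard deviation of archetype log-hazard entries
#'   (log hazard per SD of biomarker; > 0).
#' @param within_archetype_noise Standard deviation of each disease's
#'   perturbation around its archetype (>= 0).
#' @param sparsity Fraction of each archetype's entries forced to exactly
#'   zero, in [0, 1].
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(n_archetypes = 4L, n_diseases = 40L,
                           n_biomarkers = 20L, effect_scale = 0.25,
                           within_archetype_noise = 0.02, sparsity = 0.3) {
  n_archetypes <- as.integer(n_archetypes)
  n_diseases <- as.integer(n_diseases)
  n_biomarkers <- as.integer(n_biomarkers)
  if (n_archetypes < 1L) stop("n_archetypes must be >= 1")
  if (n_diseases < n_archetypes)
    stop("n_diseases (", n_diseases, ") must be >= n_archetypes (",
         n_archetypes, ")")
  if (n_biomarkers < 1L) stop("n_biomarkers must be >= 1")
  if (effect_scale <= 0) stop("effect_scale must be > 0")
  if (within_archetype_noise < 0) stop("within_archetype_noise must be >= 0")
  if (sparsity < 0 || sparsity > 1) stop("sparsity must be in [0, 1]")
  structure(list(n_archetypes = n_archetypes, n_diseases = n_diseases,
                 n_biomarkers = n_biomarkers, effect_scale = effect_scale,
                 within_archetype_noise = within_archetype_noise,
                 sparsity = sparsity),
            class = "archetype_spec")
}

#' Generate a correlated biomarker panel
#'
#' Draws a multivariate-normal biomarker matrix with block-diagonal
#' correlation: biomarkers within a block are equicorrelated at
#' `block_correlation`, biomarkers in different blocks are independent.
#' Columns have population mean 0 and variance 1. This emulates the redundancy
#' of clinical chemistry panels so that the downstream correlation-pruning
#' step has something to remove.
#'
#' @param n_subjects Number of rows.
#' @param n_biomarkers Number of columns.
#' @param block_correlation Within-block correlation, in [0, 1).
#' @param n_blocks Number of blocks (columns are split as evenly as possible).
#' @param seed Integer seed; the draw is a pure function of the arguments.
#' @return Numeric matrix `n_subjects x n_biomarkers` with columns
#'   `bm01, bm02, ...`.
#' @export
generate_biomarkers <- function(n_subjects, n_biomarkers,
                                block_correlation = 0.3, n_blocks = 4L,
                                seed = 1L) {
  if (n_blocks > n_biomarkers)
    stop("n_blocks (", n_blocks, ") must be <= n_biomarkers (", n_biomarkers, ")")
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must be in [0, 1); got ", block_correlation,
         " (equicorrelation outside this range is not positive definite)")
  set.seed(seed)
  sizes <- diff(round(seq(0, n_biomarkers, length.out = n_blocks + 1L)))
  x <- matrix(0, n_subjects, n_biomarkers)
  col0 <- 0L
  for (b in seq_len(n_blocks)) {
    p <- sizes[b]
    if (p == 0L) next
    # equicorrelated block: x = sqrt(rho) * shared + sqrt(1-rho) * idiosyncratic
    shared <- stats::rnorm(n_subjects)
    z <- matrix(stats::rnorm(n_subjects * p), n_subjects, p)
    x[, col0 + seq_len(p)] <-
      sqrt(block_correlation) * shared + sqrt(1 - block_correlation) * z
    col0 <- col0 + p
  }
  colnames(x) <- sprintf("bm%02d", seq_len(n_biomarkers))
  x
}

#' Generate planted per-disease log-hazard coefficients
#'
#' Draws one coefficient vector per archetype (with `sparsity` of entries set
#' to exactly zero) and derives each disease's true coefficient vector as its
#' archetype plus independent Gaussian perturbation. The archetype assignment
#' is the ground-truth cluster label used by all recovery tests.
#'
#' @param spec An [archetype_spec()].
#' @param seed Integer seed.
#' @return List with `beta` (matrix `n_diseases x n_biomarkers` of true
#'   log-hazards, rows `D001, ...`), `cluster` (integer archetype label per
#'   disease) and `archetypes` (the archetype matrix itself).
#' @export
generate_disease_effects <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "archetype_spec"))
  set.seed(seed)
  k <- spec$n_archetypes; m <- spec$n_diseases; p <- spec$n_biomarkers
  arch <- matrix(stats::rnorm(k * p, sd = spec$effect_scale), k, p)
  n_zero <- round(spec$sparsity * p)
  if (n_zero > 0) {
    for (a in seq_len(k)) {
      arch[a, sample.int(p, n_zero)] <- 0
    }
  }
  labels <- sort(rep(seq_len(k), length.out = m))
  beta <- arch[labels, , drop = FALSE] +
    matrix(stats::rnorm(m * p, sd = spec$within_archetype_noise), m, p)
  rownames(beta) <- sprintf("D%03d", seq_len(m))
  colnames(beta) <- sprintf("bm%02d", seq_len(p))
  list(beta = beta, cluster = stats::setNames(labels, rownames(beta)),
       archetypes = arch)
}

#' Simulate right-censored time-to-first-diagnosis outcomes
#'
#' Each disease is simulated independently given the shared biomarker matrix:
#' onset time is exponential with subject rate `baseline_rate *
#' exp(x' beta + offset)` (constant baseline hazard, so the proportional
#' hazards model that will be fitted downstream is exactly true and the
#' marginal event rate has a closed form). Administrative censoring is applied
#' at `horizon`.
#'
#' @param biomarkers Matrix `n x p` of (standardized) biomarker values.
#' @param covariate_effects Per-subject additive log-hazard offset coming from
#'   the fixed covariates (scalar or length-n vector); 0 for none.
#' @param true_betas Matrix `m x p` of per-disease log-hazard coefficients.
#' @param baseline_rate Baseline events per person-year (> 0).
#' @param horizon Administrative censoring horizon in years (> 0).
#' @param seed Integer seed.
#' @return List with `time` and `event` matrices (`n x m`, disease columns
#'   named as `rownames(true_betas)`). Times are in (0, horizon]; `event` is
#'   0/1 with 0 meaning censored at the horizon.
#' @export
simulate_survival <- function(biomarkers, covariate_effects = 0, true_betas,
                              baseline_rate = 0.01, horizon = 12, seed = 1L) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (horizon <= 0) stop("horizon must be > 0")
  lp <- biomarkers %*% t(true_betas)           # n x m
  lp <- sweep(lp, 1L, covariate_effects, "+")
  rate <- baseline_rate * exp(lp)
  if (any(!is.finite(rate)))
    stop("exp(x'beta) overflowed; use a smaller effect_scale or covariate effects")
  set.seed(seed)
  n <- nrow(biomarkers); m <- nrow(true_betas)
  onset <- matrix(stats::rexp(n * m), n, m) / rate
  event <- (onset <= horizon) * 1L
  time <- pmin(onset, horizon)
  # guard against zero times from underflow at extreme rates
  time[time <= 0] <- .Machine$double.eps
  dimnames(time) <- dimnames(event) <- list(NULL, rownames(true_betas))
  list(time = time, event = event)
}

#' Simulate an independent EHR-style disease co-occurrence table
#'
#' Generates binary presence/absence indicators for `m` diseases whose
#' pairwise odds structure is concordant with the planted clusters: each
#' subject carries a latent binary susceptibility per cluster (probability
#' `susceptible_fraction`), diseases of a susceptible cluster occur with
#' elevated probability, and diseases in different clusters are independent.
#' The disease probabilities are solved so that the marginal prevalence
#' equals `base_prevalence` and the marginal odds ratio between two diseases
#' of the same cluster equals `within_cluster_or`.
#'
#' @param true_cluster_labels Integer cluster label per disease (names become
#'   disease identifiers).
#' @param n_subjects Number of rows.
#' @param base_prevalence Marginal prevalence of every disease, in (0, 1).
#' @param within_cluster_or Target marginal odds ratio for same-cluster
#'   disease pairs (>= 1); 1 gives full independence.
#' @param susceptible_fraction Probability that a subject is susceptible to a
#'   given cluster, in (0, 1); smaller values allow larger odds ratios at a
#'   fixed prevalence.
#' @param seed Integer seed.
#' @return Integer 0/1 matrix `n_subjects x m` of class `ehr_table` with an
#'   attribute `cluster` carrying the generating labels.
#' @export
simulate_ehr <- function(true_cluster_labels, n_subjects,
                         base_prevalence = 0.15, within_cluster_or = 2,
                         susceptible_fraction = 0.25, seed = 1L) {
  if (base_prevalence <= 0 || base_prevalence >= 1)
    stop("base_prevalence must be in (0, 1)")
  if (within_cluster_or < 1) stop("within_cluster_or must be >= 1")
  if (susceptible_fraction <= 0 || susceptible_fraction >= 1)
    stop("susceptible_fraction must be in (0, 1)")
  pi0 <- base_prevalence
  q <- susceptible_fraction
  spread <- .solve_cluster_spread(pi0, within_cluster_or, q)
  p_hi <- pi0 + (1 - q) * spread
  p_lo <- pi0 - q * spread
  if (p_lo <= 0 || p_hi >= 1)
    stop("within_cluster_or = ", within_cluster_or, " with base_prevalence = ",
         pi0, " implies disease probabilities outside (0, 1)")
  labs <- true_cluster_labels
  m <- length(labs)
  dn <- names(labs)
  if (is.null(dn)) dn <- sprintf("D%03d", seq_len(m))
  set.seed(seed)
  clusters <- sort(unique(labs))
  suscept <- matrix(stats::rbinom(n_subjects * length(clusters), 1L, q),
                    n_subjects, length(clusters),
                    dimnames = list(NULL, as.character(clusters)))
  prob <- matrix(p_lo, n_subjects, m)
  for (j in seq_len(m)) {
    s <- suscept[, as.character(labs[j])]
    prob[s == 1L, j] <- p_hi
  }
  x <- matrix(stats::rbinom(n_subjects * m, 1L, as.vector(prob)), n_subjects, m)
  colnames(x) <- dn
  if (all(colSums(x) == 0L))
    stop("no disease has any case; increase n_subjects or base_prevalence")
  structure(x, cluster = stats::setNames(labs, dn), class = c("ehr_table", "matrix"))
}

# Solve for the spread D of the two-point disease-probability mixture
# (p = pi0 + (1-q)D with probability q, p = pi0 - qD otherwise) that yields
# the requested marginal odds ratio between two diseases sharing the latent
# susceptibility. The mixture variance v = q(1-q)D^2 drives the joint cell
# probabilities: P11 = pi0^2 + v, P10 = P01 = pi0(1-pi0) - v,
# P00 = (1-pi0)^2 + v, and the odds ratio is increasing in v.
.solve_cluster_spread <- function(pi0, or, q) {
  if (or == 1) return(0)
  or_of <- function(d) {
    v <- q * (1 - q) * d^2
    p11 <- pi0^2 + v
    p10 <- pi0 * (1 - pi0) - v
    p00 <- (1 - pi0)^2 + v
    (p11 * p00) / (p10 * p10)
  }
  upper <- min(pi0 / q, (1 - pi0) / (1 - q)) - 1e-9
  if (or_of(upper) < or)
    stop("within_cluster_or = ", or, " unattainable at base_prevalence = ",
         pi0, " with susceptible_fraction = ", q)
  stats::uniroot(function(d) or_of(d) - or, c(0, upper), tol = 1e-12)$root
}

#' Simulate a full synthetic cohort
#'
#' Bundles covariate generation, the correlated biomarker panel, planted
#' disease effects and per-disease survival outcomes into one cohort object.
#' Covariates emulate a mid-life population cohort: age ~ U(40, 70), sex ~
#' Bernoulli(0.5), deprivation index ~ N(0, 3), BMI ~ N(27, 4) kg/m^2,
#' smoking ~ Bernoulli(0.45), systolic BP ~ N(138, 18) mmHg. Covariates enter
#' the hazard through `covariate_coefs` plus an optional nonlinear age term
#' (`age_poly`, coefficients of centered-age powers) for the downstream age
#' spline to absorb. Optionally the first two biomarkers are made strongly
#' sex-dependent to exercise the sex-linked-marker exclusion rule.
#'
#' @param n_subjects Number of subjects.
#' @param spec An [archetype_spec()].
#' @param block_correlation,n_blocks Passed to [generate_biomarkers()].
#' @param covariate_coefs Named log-hazard coefficients for
#'   `sex, deprivation, bmi, smoking, sbp` (applied to standardized bmi/sbp
#'   and raw binaries).
#' @param age_poly Coefficients of ((age - 55)/10)^1..k in the log hazard.
#' @param sex_linked_biomarkers If TRUE, add +/- 1.5 SD sex shifts to the
#'   first two biomarkers.
#' @param baseline_rate,horizon Passed to [simulate_survival()].
#' @param seed Integer seed.
#' @return Object of class `cohort_table`: list with `covariates`
#'   (data.frame), `biomarkers` (matrix), `time`/`event` (matrices n x m),
#'   `truth` (list: `beta`, `cluster`, `sex_linked`), and the generation
#'   parameters.
#' @export
simulate_cohort <- function(n_subjects, spec = archetype_spec(),
                            block_correlation = 0.3, n_blocks = 4L,
                            covariate_coefs = c(sex = 0.1, deprivation = 0.02,
                                                bmi = 0.1, smoking = 0.15,
                                                sbp = 0.1),
                            age_poly = c(0.3, 0.1),
                            sex_linked_biomarkers = FALSE,
                            baseline_rate = 0.01, horizon = 12, seed = 1L) {
  stopifnot(inherits(spec, "archetype_spec"))
  bm <- generate_biomarkers(n_subjects, spec$n_biomarkers,
                            block_correlation, n_blocks, seed = seed)
  set.seed(seed + 1L)
  cov <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n_subjects)),
    age = stats::runif(n_subjects, 40, 70),
    sex = stats::rbinom(n_subjects, 1L, 0.5),
    deprivation = stats::rnorm(n_subjects, 0, 3),
    bmi = stats::rnorm(n_subjects, 27, 4),
    smoking = stats::rbinom(n_subjects, 1L, 0.45),
    sbp = stats::rnorm(n_subjects, 138, 18)
  )
  sex_linked <- character(0)
  if (sex_linked_biomarkers && spec$n_biomarkers >= 2) {
    sex_linked <- colnames(bm)[1:2]
    bm[, 1] <- bm[, 1] + 1.5 * cov$sex
    bm[, 2] <- bm[, 2] - 1.5 * cov$sex
  }
  eff <- generate_disease_effects(spec, seed = seed + 2L)
  agec <- (cov$age - 55) / 10
  offset <- drop(outer(agec, seq_along(age_poly), "^") %*% age_poly) +
    covariate_coefs[["sex"]] * cov$sex +
    covariate_coefs[["deprivation"]] * cov$deprivation +
    covariate_coefs[["bmi"]] * (cov$bmi - 27) / 4 +
    covariate_coefs[["smoking"]] * cov$smoking +
    covariate_coefs[["sbp"]] * (cov$sbp - 138) / 18
  out <- simulate_survival(bm, offset, eff$beta, baseline_rate, horizon,
                           seed = seed + 3L)
  structure(list(covariates = cov, biomarkers = bm,
                 time = out$time, event = out$event,
                 truth = list(beta = eff$beta, cluster = eff$cluster,
                              sex_linked = sex_linked),
                 params = list(spec = spec, baseline_rate = baseline_rate,
                               horizon = horizon, seed = seed)),
            class = "cohort_table")
}

#' Assemble a cohort object from its parts
#'
#' Low-level constructor for users who generate biomarkers, covariates and
#' outcomes separately (e.g. with [generate_biomarkers()] and
#' [simulate_survival()]) and want the container the modeling functions
#' expect.
#'
#' @param covariates data.frame with columns `age`, `sex`, `deprivation`,
#'   `bmi`, `smoking`, `sbp` (a `subject_id` is added if absent).
#' @param biomarkers Numeric matrix, one row per subject.
#' @param time,event Outcome matrices (subjects x diseases, shared dimnames).
#' @param truth Optional list with `beta` and `cluster` ground truth.
#' @param params Optional list of generation parameters.
#' @return Object of class `cohort_table`.
#' @export
cohort_table <- function(covariates, biomarkers, time, event, truth = NULL,
                         params = NULL) {
  stopifnot(nrow(covariates) == nrow(biomarkers),
            nrow(biomarkers) == nrow(time),
            all(dim(time) == dim(event)))
  if (is.null(covariates$subject_id))
    covariates$subject_id <- sprintf("S%06d", seq_len(nrow(covariates)))
  structure(list(covariates = covariates, biomarkers = biomarkers,
                 time = time, event = event, truth = truth, params = params),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$biomarkers), "subjects,",
      ncol(x$biomarkers), "biomarkers,", ncol(x$time), "diseases\n")
  cat("Events per disease: median", stats::median(colSums(x$event)),
      "(range", paste(range(colSums(x$event)), collapse = "-"), ")\n")
  invisible(x)
}
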