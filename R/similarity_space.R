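#' Extract the biomarker-only log-hazard submatrix
#'
#' Removes every fixed (non-biomarker) covariate column from the hazard
#' matrix, plus any explicitly excluded biomarkers (e.g. strongly sex-linked
#' markers), and converts the weighted hazard ratios to the log scale so that
#' protective and risk effects are symmetric around zero.
#'
#' @param hazards A `hazard_matrix` (see [build_hazard_matrix()]) or a plain
#'   diseases x covariates HR matrix with a `fixed_covariates` attribute.
#' @param exclusions Biomarker column names to drop (must exist).
#' @return Diseases x biomarkers matrix of log hazard ratios.
#' @export
biomarker_submatrix <- function(hazards, exclusions = character(0)) {
  if (inherits(hazards, "hazard_matrix")) {
    hr <- hazards$hr
    fixed <- hazards$fixed_covariates
  } else {
    hr <- hazards
    fixed <- attr(hazards, "fixed_covariates") %||% character(0)
  }
  missing_cols <- setdiff(exclusions, colnames(hr))
  if (length(missing_cols))
    stop("exclusion(s) not present in hazard matrix: ",
         paste(missing_cols, collapse = ", "))
  keep <- setdiff(colnames(hr), c(fixed, exclusions))
  if (!length(keep)) stop("no biomarker columns remain after exclusions")
  log(hr[, keep, drop = FALSE])
}

#' Disease-disease correlation of biomarker risk profiles
#'
#' Pearson correlation between every pair of disease rows across biomarker
#' dimensions. Diseases with a constant profile get zero correlations (with a
#' warning) since their correlation is undefined.
#'
#' @param submatrix Diseases x biomarkers log-HR matrix (>= 3 biomarkers).
#' @return Symmetric m x m correlation matrix with unit diagonal.
#' @export
disease_correlation <- function(submatrix) {
  if (ncol(submatrix) < 3) stop("need at least 3 biomarker columns")
  const <- apply(submatrix, 1L, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(t(submatrix)))
  if (any(const)) {
    warning("constant risk profile(s), correlations set to 0: ",
            paste(rownames(submatrix)[const], collapse = ", "))
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc[is.na(cc)] <- 0
  (cc + t(cc)) / 2
}

# Permute a matrix: independently shuffle the entries within each row
# (every disease keeps its set of effect sizes, loses biomarker identity),
# or shuffle the whole matrix globally.
.permute_hazards <- function(x, scheme = c("within_row", "global")) {
  scheme <- match.arg(scheme)
  if (scheme == "global") {
    out <- matrix(sample(x), nrow(x), ncol(x), dimnames = dimnames(x))
  } else {
    out <- t(apply(x, 1L, sample))
    dimnames(out) <- dimnames(x)
  }
  out
}

#' Permutation null for disease profile correlations
#'
#' Estimates the probability that the correlation between two permuted
#' biomarker risk profiles exceeds a cutoff. Each permutation independently
#' shuffles the entries within each disease row (the most conservative null
#' that preserves per-disease effect-size distributions); a global-shuffle
#' alternative is available. The tail probability is the fraction of permuted
#' off-diagonal correlations exceeding the cutoff; its confidence interval is
#' a t-interval over the per-permutation exceedance fractions (correlations
#' within one permutation share rows and are dependent, so a plain binomial
#' interval over all draws would be too narrow).
#'
#' @param submatrix Diseases x biomarkers log-HR matrix.
#' @param cutoff Correlation cutoff, strictly inside (-1, 1).
#' @param n_permutations Number of permuted matrices (>= 100).
#' @param seed Integer seed.
#' @param scheme `"within_row"` (default) or `"global"`.
#' @param conf_level Confidence level of the binomial interval.
#' @return List with `tail_probability`, `conf_int`, `n_exceed`, `n_draws`,
#'   `cutoff`, `scheme`.
#' @export
correlation_permutation_null <- function(submatrix, cutoff = 0.25,
                                         n_permutations = 200L, seed = 1L,
                                         scheme = c("within_row", "global"),
                                         conf_level = 0.95) {
  if (cutoff <= -1 || cutoff >= 1) stop("cutoff must be inside (-1, 1)")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  scheme <- match.arg(scheme)
  set.seed(seed)
  m <- nrow(submatrix)
  ut <- upper.tri(matrix(0, m, m))
  frac <- numeric(n_permutations)
  n_exceed <- 0L; n_draws <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- .permute_hazards(submatrix, scheme)
    r <- suppressWarnings(stats::cor(t(perm)))[ut]
    r <- r[!is.na(r)]
    frac[b] <- mean(r > cutoff)
    n_exceed <- n_exceed + sum(r > cutoff)
    n_draws <- n_draws + length(r)
  }
  est <- mean(frac)
  se <- stats::sd(frac) / sqrt(n_permutations)
  halfw <- stats::qt(1 - (1 - conf_level) / 2, n_permutations - 1L) * se
  list(tail_probability = est, conf_int = c(est - halfw, est + halfw),
       n_exceed = n_exceed, n_draws = n_draws,
       n_permutations = n_permutations, cutoff = cutoff, scheme = scheme)
}

# ---- graphical lasso -------------------------------------------------------

# Lasso sub-problem of the graphical lasso, solved by coordinate descent:
# minimize (1/2) b' V b - s' b + rho * ||b||_1.
.glasso_cd <- function(V, s, rho, b, tol = 1e-6, max_iter = 500L) {
  p <- length(s)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      x <- s[j] - sum(V[j, ] * b) + V[j, j] * b[j]
      bj <- sign(x) * max(abs(x) - rho, 0) / V[j, j]
      delta <- max(delta, abs(bj - b[j]))
      b[j] <- bj
    }
    if (delta < tol) break
  }
  b
}

#' Graphical lasso estimate of a sparse precision matrix
#'
#' Blockwise coordinate-descent graphical lasso (Friedman, Hastie &
#' Tibshirani 2008): maximizes the L1-penalized Gaussian log-likelihood
#' `log det Theta - tr(S Theta) - rho ||Theta||_1` over positive-definite
#' precision matrices.
#'
#' @param S Sample covariance matrix (p x p, symmetric).
#' @param rho Penalty (>= 0; the diagonal is not penalized).
#' @param tol Convergence tolerance on the average absolute change of the
#'   covariance estimate per sweep.
#' @param max_iter Maximum outer sweeps.
#' @return List with `theta` (precision) and `w` (covariance) estimates.
#' @export
glasso_fit <- function(S, rho, tol = 1e-5, max_iter = 100L) {
  p <- nrow(S)
  W <- S + rho * diag(p)
  B <- matrix(0, p - 1L, p)     # warm-started regression coefficients
  mean_off <- mean(abs(S[upper.tri(S)]))
  thresh <- tol * max(mean_off, .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      V <- W[idx, idx, drop = FALSE]
      s <- S[idx, j]
      b <- .glasso_cd(V, s, rho, B[, j])
      B[, j] <- b
      w12 <- V %*% b
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (mean(abs(W - W_old)) < thresh) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  Theta <- (Theta + t(Theta)) / 2
  dimnames(Theta) <- dimnames(W) <- dimnames(S)
  list(theta = Theta, w = W)
}

# Precision -> partial correlation, diagonal set to 0 (self-edges suppressed).
.theta_to_pcor <- function(theta) {
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  diag(pc) <- 0
  pc
}

#' Sparse partial-correlation network of disease space
#'
#' Treats diseases as variables and biomarker dimensions as observations,
#' estimates a sparse precision matrix over diseases by the graphical lasso
#' with the penalty chosen by K-fold cross-validation over biomarker
#' dimensions (held-out Gaussian log-likelihood), converts it to partial
#' correlations, and reports the edges exceeding a magnitude threshold.
#'
#' @param submatrix Diseases x biomarkers log-HR matrix (> 2 biomarkers).
#' @param cv_folds Number of CV folds over biomarker dimensions (>= 2).
#' @param edge_threshold Edges with `|partial correlation| <=` this value are
#'   dropped from the edge list (the full matrix is retained).
#' @param seed Integer seed (fold assignment).
#' @param rho_grid Optional penalty grid; default is 15 log-spaced values
#'   scaled to the data.
#' @return List with `pcor` (m x m partial-correlation matrix, zero diagonal),
#'   `edges` (data.frame `source`, `target`, `weight`), `rho` (chosen
#'   penalty), `cv_loglik` (per-penalty mean held-out log-likelihood).
#' @export
partial_correlation_network <- function(submatrix, cv_folds = 5L,
                                        edge_threshold = 0.1, seed = 1L,
                                        rho_grid = NULL) {
  m <- nrow(submatrix); p <- ncol(submatrix)
  if (p <= 2) stop("need more than 2 biomarker columns")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  x <- t(submatrix)                       # observations (biomarkers) x diseases
  x <- scale(x, center = TRUE, scale = FALSE)
  S_full <- stats::cov(x)
  if (is.null(rho_grid)) {
    rho_max <- max(abs(S_full[upper.tri(S_full)]))
    rho_grid <- exp(seq(log(rho_max), log(rho_max * 0.01), length.out = 15))
  }
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), p))
  loglik <- matrix(NA_real_, cv_folds, length(rho_grid))
  for (k in seq_len(cv_folds)) {
    xtr <- x[folds != k, , drop = FALSE]
    xte <- x[folds == k, , drop = FALSE]
    S_tr <- stats::cov(xtr)
    S_te <- crossprod(xte) / nrow(xte)
    for (g in seq_along(rho_grid)) {
      fit <- .glasso_safe(S_tr, rho_grid[g])
      if (is.null(fit)) next
      ld <- determinant(fit$theta, logarithm = TRUE)
      if (ld$sign <= 0) next
      loglik[k, g] <- as.numeric(ld$modulus) - sum(S_te * fit$theta)
    }
  }
  mean_ll <- colMeans(loglik, na.rm = TRUE)
  if (all(!is.finite(mean_ll)))
    stop("graphical lasso failed to converge on every penalty")
  best <- which.max(mean_ll)
  fit <- .glasso_safe(S_full, rho_grid[best])
  if (is.null(fit)) stop("graphical lasso failed at the selected penalty")
  pcor <- .theta_to_pcor(fit$theta)
  dimnames(pcor) <- list(rownames(submatrix), rownames(submatrix))
  ut <- which(upper.tri(pcor) & abs(pcor) > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(source = rownames(pcor)[ut[, 1]],
                      target = rownames(pcor)[ut[, 2]],
                      weight = pcor[ut])
  list(pcor = pcor, edges = edges, rho = rho_grid[best],
       cv_loglik = stats::setNames(mean_ll, signif(rho_grid, 4)))
}

# Run glasso_fit, retrying on a damped (inflated-diagonal) covariance if the
# estimate is not positive definite; NULL on persistent failure.
.glasso_safe <- function(S, rho) {
  for (damp in c(0, 1e-4, 1e-2)) {
    fit <- tryCatch(glasso_fit(S + damp * mean(diag(S)) * diag(nrow(S)), rho),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      ev <- suppressWarnings(min(eigen(fit$theta, symmetric = TRUE,
                                       only.values = TRUE)$values))
      if (is.finite(ev) && ev > 0) return(fit)
    }
  }
  NULL
}

#' Full similarity analysis of a hazard matrix
#'
#' Convenience wrapper: biomarker submatrix, disease correlation matrix,
#' permutation-null tail estimate and partial-correlation network in one call.
#'
#' @inheritParams biomarker_submatrix
#' @inheritParams correlation_permutation_null
#' @inheritParams partial_correlation_network
#' @return Object of class `similarity_result`.
#' @export
similarity_analysis <- function(hazards, exclusions = character(0),
                                cutoff = 0.25, n_permutations = 200L,
                                cv_folds = 5L, edge_threshold = 0.1,
                                seed = 1L) {
  sub <- biomarker_submatrix(hazards, exclusions)
  structure(list(
    submatrix = sub,
    correlation = disease_correlation(sub),
    null = correlation_permutation_null(sub, cutoff, n_permutations, seed),
    network = partial_correlation_network(sub, cv_folds, edge_threshold, seed)
  ), class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("Similarity over", nrow(x$submatrix), "diseases x", ncol(x$submatrix),
      "biomarkers; P(permuted r >", x$null$cutoff, ") =",
      signif(x$null$tail_probability, 3), ";", nrow(x$network$edges),
      "network edges\n")
  invisible(x)
}
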