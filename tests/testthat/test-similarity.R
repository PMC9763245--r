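make_hazard_stub <- function(loghr, fixed = NULL) {
  # plain HR matrix carrying the fixed-covariate attribute
  hr <- exp(loghr)
  if (!is.null(fixed)) attr(hr, "fixed_covariates") <- fixed
  hr
}

test_that("biomarker submatrix drops fixed covariates and takes logs", {
  set.seed(1)
  lh <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("D001", "D002", "D003"),
                               c("age_bs1", "sex", "bm01", "bm02")))
  hr <- make_hazard_stub(lh, fixed = c("age_bs1", "sex"))
  sub <- biomarker_submatrix(hr)
  expect_identical(colnames(sub), c("bm01", "bm02"))
  expect_equal(sub, lh[, c("bm01", "bm02")])

  # exclusions remove named biomarkers
  sub2 <- biomarker_submatrix(hr, exclusions = "bm01")
  expect_identical(colnames(sub2), "bm02")
  expect_error(biomarker_submatrix(hr, exclusions = "nope"), "not present")
  expect_error(biomarker_submatrix(hr, exclusions = c("bm01", "bm02")),
               "no biomarker columns")
})

test_that("disease correlation has exact values on constructed profiles", {
  base <- c(0.2, -0.1, 0.4, 0, 0.3)
  x <- rbind(A = base,
             B = 2 * base + 0.05,        # affine copy: r = 1
             C = -base,                  # negation: r = -1
             D = rep(0.1, 5))            # constant: undefined -> 0
  expect_warning(cc <- disease_correlation(x), "constant")
  expect_equal(unname(diag(cc)), rep(1, 4))
  expect_equal(cc["A", "B"], 1)
  expect_equal(cc["A", "C"], -1)
  expect_equal(unname(cc["D", c("A", "B", "C")]), rep(0, 3))
  expect_identical(cc, t(cc))

  # cross-check against stats::cor on a random matrix
  set.seed(2)
  y <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(sprintf("D%02d", 1:8)))
  expect_equal(disease_correlation(y), cor(t(y)))
  expect_error(disease_correlation(y[, 1:2]), "at least 3")
})

test_that("permutation null hits trivial cutoffs and is reproducible", {
  set.seed(3)
  x <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("D%02d", 1:10), NULL))
  # cutoff near 1: essentially no permuted correlation exceeds it
  hi <- correlation_permutation_null(x, cutoff = 0.9999,
                                     n_permutations = 100, seed = 4)
  expect_equal(hi$tail_probability, 0)
  # cutoff near -1: essentially all exceed it
  lo <- correlation_permutation_null(x, cutoff = -0.9999,
                                     n_permutations = 100, seed = 4)
  expect_equal(lo$tail_probability, 1)
  expect_equal(lo$n_exceed, lo$n_draws)

  a <- correlation_permutation_null(x, 0.25, 100, seed = 5)
  b <- correlation_permutation_null(x, 0.25, 100, seed = 5)
  expect_identical(a, b)
  expect_true(a$conf_int[1] <= a$tail_probability &&
                a$tail_probability <= a$conf_int[2])
  expect_equal(a$n_draws, 100 * choose(10, 2))

  expect_error(correlation_permutation_null(x, cutoff = 1), "cutoff")
  expect_error(correlation_permutation_null(x, 0.25, n_permutations = 10),
               "n_permutations")
})

test_that("glasso at a near-zero penalty matches direct inversion (corpcor)", {
  set.seed(6)
  p <- 6; n <- 500
  z <- matrix(rnorm(n * p), n, p)
  z[, 2] <- 0.6 * z[, 1] + 0.8 * z[, 2]
  S <- cov(z)
  fit <- glasso_fit(S, rho = 1e-8, tol = 1e-9, max_iter = 500)
  # precision approximates solve(S)
  expect_equal(fit$theta, solve(S), tolerance = 1e-4)
  # partial correlations match the shrinkage-free corpcor computation
  pc_ref <- corpcor::cor2pcor(S)
  pc_ours <- -fit$theta / tcrossprod(sqrt(diag(fit$theta)))
  diag(pc_ours) <- 1
  expect_equal(unname(pc_ours), unname(pc_ref), tolerance = 1e-4)
})

test_that("glasso penalty monotonically sparsifies and keeps PD estimates", {
  set.seed(7)
  z <- matrix(rnorm(300 * 5), 300, 5)
  S <- cov(z)
  nz <- sapply(c(0.01, 0.1, 0.5), function(r) {
    th <- glasso_fit(S, r)$theta
    expect_gt(min(eigen(th, symmetric = TRUE, only.values = TRUE)$values), 0)
    sum(abs(th[upper.tri(th)]) > 1e-8)
  })
  expect_true(all(diff(nz) <= 0))
  # a large penalty wipes out all off-diagonal structure
  th_big <- glasso_fit(S, 10)$theta
  expect_lt(max(abs(th_big[upper.tri(th_big)])), 1e-8)
})

test_that("partial-correlation network recovers a planted A-B-C chain", {
  # A -> B -> C chain: A and C are marginally correlated but conditionally
  # independent given B, so |pcor(A,C)| should be the smallest of the three.
  recovered <- 0
  for (s in 1:10) {
    set.seed(s)
    nobs <- 60
    b <- rnorm(nobs)
    a <- 0.8 * b + sqrt(1 - 0.64) * rnorm(nobs)
    cc <- 0.8 * b + sqrt(1 - 0.64) * rnorm(nobs)
    sub <- t(cbind(A = a, B = b, C = cc))   # diseases x biomarker dims
    colnames(sub) <- NULL
    net <- partial_correlation_network(sub, cv_folds = 5, seed = s)
    p <- abs(net$pcor)
    if (p["A", "C"] < p["A", "B"] && p["A", "C"] < p["B", "C"])
      recovered <- recovered + 1
  }
  expect_gte(recovered, 9)
})

test_that("network support respects a two-block independence structure", {
  set.seed(111)
  nobs <- 200
  # two independent blocks of 3 diseases sharing a latent factor each
  f1 <- rnorm(nobs); f2 <- rnorm(nobs)
  sub <- t(cbind(A = f1 + 0.4 * rnorm(nobs), B = f1 + 0.4 * rnorm(nobs),
                 C = f1 + 0.4 * rnorm(nobs), D = f2 + 0.4 * rnorm(nobs),
                 E = f2 + 0.4 * rnorm(nobs), F = f2 + 0.4 * rnorm(nobs)))
  net <- partial_correlation_network(sub, cv_folds = 5, seed = 12)
  cross <- net$edges$source %in% c("A", "B", "C") !=
    net$edges$target %in% c("A", "B", "C")
  expect_gt(nrow(net$edges), 0)
  expect_equal(sum(cross), 0)
  # pcor has zero diagonal and symmetric entries
  expect_equal(unname(diag(net$pcor)), rep(0, 6))
  expect_equal(net$pcor, t(net$pcor), tolerance = 1e-10)

  # an impossible edge threshold empties the edge list but not the matrix
  net1 <- partial_correlation_network(sub, cv_folds = 5, seed = 12,
                                      edge_threshold = 1)
  expect_equal(nrow(net1$edges), 0)
  expect_equal(net1$pcor, net$pcor)
  expect_error(partial_correlation_network(sub[, 1:2], cv_folds = 2),
               "more than 2")
  expect_error(partial_correlation_network(sub, cv_folds = 1), "cv_folds")
})

test_that("similarity_analysis wraps the three components consistently", {
  set.seed(13)
  lh <- matrix(rnorm(9 * 20, sd = 0.3), 9, 20,
               dimnames = list(sprintf("D%03d", 1:9),
                               sprintf("bm%02d", 1:20)))
  hr <- make_hazard_stub(lh)
  res <- similarity_analysis(hr, n_permutations = 100, seed = 14)
  expect_s3_class(res, "similarity_result")
  expect_equal(res$submatrix, lh)
  expect_equal(res$correlation, disease_correlation(lh))
  expect_identical(
    res$null,
    correlation_permutation_null(lh, 0.25, 100, seed = 14))
  expect_output(print(res), "Similarity over 9 diseases")
})
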