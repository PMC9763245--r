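# Shared fixture builders. Everything is generated in code at test time.

# Cohort with fully controlled true coefficients (one row per disease) and a
# zero covariate contribution, so closed-form oracles apply.
make_cohort <- function(n, beta, seed, baseline_rate = 0.02, horizon = 12,
                        block_correlation = 0.2, offset = 0) {
  if (is.null(dim(beta))) beta <- matrix(beta, 1, length(beta),
                                         dimnames = list("D001", NULL))
  p <- ncol(beta)
  bm <- generate_biomarkers(n, p, block_correlation, n_blocks = 2L, seed = seed)
  colnames(beta) <- colnames(bm)
  set.seed(seed + 100L)
  cov <- data.frame(
    age = stats::runif(n, 40, 70), sex = stats::rbinom(n, 1, 0.5),
    deprivation = stats::rnorm(n, 0, 3), bmi = stats::rnorm(n, 27, 4),
    smoking = stats::rbinom(n, 1, 0.45), sbp = stats::rnorm(n, 138, 18)
  )
  out <- simulate_survival(bm, offset, beta, baseline_rate, horizon,
                           seed = seed + 200L)
  cohort_table(cov, bm, out$time, out$event,
               truth = list(beta = beta,
                            cluster = stats::setNames(rep(1L, nrow(beta)),
                                                      rownames(beta))))
}

# Exhaustive-pair concordance oracle (independent of the package's
# implementation path): loops over all ordered pairs.
concordance_oracle <- function(risk, times, events) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || events[i] != 1) next
    comparable <- times[j] > times[i] ||
      (times[j] == times[i] && events[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Small hand-set association matrix + labels used by the TMR fixtures:
# 4 diseases, 2 clusters {A,B} and {C,D}; pair associations (max of the two
# directions): AB=0.8 (match), AC=0.6 (non-match), CD=0.5 (match),
# BD=0.05, AD=0.02, BC=0.
tmr_fixture <- function() {
  dn <- c("A", "B", "C", "D")
  co <- matrix(0, 4, 4, dimnames = list(dn, dn))
  co["A", "B"] <- 0.8; co["B", "A"] <- 0.7
  co["A", "C"] <- 0.6; co["C", "A"] <- 0.1
  co["C", "D"] <- 0.5; co["D", "C"] <- 0.4
  co["B", "D"] <- 0.05; co["A", "D"] <- 0.02
  diag(co) <- NA_real_
  labels <- c(A = 1L, B = 1L, C = 2L, D = 2L)
  list(assoc = co, labels = labels)
}
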