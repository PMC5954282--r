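## Shared fixtures (built once per test run) and independent oracles.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

## Small labeled cohort with sentinels, shared by several test files.
small_cohort <- function() fixture("small_cohort", function() {
  ch <- generate_cohort(cohort_config(n_patients = 20, n_genes = 500,
                                      seed = 301))
  generate_sentinels(ch, n_sentinels = 4, n_batches = 4, seed = 302)
})

small_prep <- function() fixture("small_prep", function() {
  prepare_training_data(small_cohort(), n_replicates = 10L)
})

## Random small count matrix with gene/sample names.
random_counts <- function(m, n, seed, lambda = 50) {
  set.seed(seed)
  matrix(rpois(m * n, lambda), m, n,
         dimnames = list(sprintf("g%03d", seq_len(m)),
                         sprintf("s%03d", seq_len(n))))
}

## Brute-force median-of-ratios oracle (explicit loops, zero-count rules
## spelled out independently of the package implementation).
brute_force_size_factors <- function(K) {
  m <- nrow(K); n <- ncol(K)
  geo <- numeric(m)
  for (g in seq_len(m)) geo[g] <- prod(K[g, ])^(1 / n)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ratios <- c()
    for (g in seq_len(m))
      if (geo[g] > 0 && K[g, i] > 0) ratios <- c(ratios, K[g, i] / geo[g])
    ## median taken in log space: an even ratio count interpolates the two
    ## middle values geometrically, matching the reference convention
    s[i] <- exp(median(log(ratios)))
  }
  names(s) <- colnames(K)
  s
}

## Brute-force AUC by pair counting with half-credit ties.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## Full-gradient proximal oracle for the elastic-net logistic objective
## (1/n) sum log(1 + exp(-(2y-1) eta)) + lambda (a |b|_1 + (1-a)/2 |b|^2),
## intercept unpenalized. Plain ISTA with a conservative step size.
prox_elastic_net <- function(x, y, lambda, mixing, iters = 50000L) {
  n <- nrow(x); p <- ncol(x)
  beta <- numeric(p); b0 <- 0
  L <- max(eigen(crossprod(x) / n, only.values = TRUE)$values) / 4 +
    lambda * (1 - mixing) + 0.25
  eta_step <- 1 / L
  for (it in seq_len(iters)) {
    eta <- drop(x %*% beta) + b0
    pr <- 1 / (1 + exp(-eta))
    grad_b <- drop(crossprod(x, pr - y)) / n + lambda * (1 - mixing) * beta
    grad_0 <- mean(pr - y)
    z <- beta - eta_step * grad_b
    thr <- eta_step * lambda * mixing
    beta_new <- sign(z) * pmax(abs(z) - thr, 0)
    b0_new <- b0 - eta_step * grad_0
    if (max(abs(beta_new - beta), abs(b0_new - b0)) < 1e-11 && it > 100) {
      beta <- beta_new; b0 <- b0_new; break
    }
    beta <- beta_new; b0 <- b0_new
  }
  list(intercept = b0, beta = beta)
}

elastic_net_objective <- function(x, y, b0, beta, lambda, mixing) {
  eta <- drop(x %*% beta) + b0
  mean(log(1 + exp(eta)) - y * eta) +
    lambda * (mixing * sum(abs(beta)) + (1 - mixing) / 2 * sum(beta^2))
}

## Acceptance-scale fixtures: one 60-patient development cohort and its
## LOPO result, shared between the pipeline-closure and audit tests.
acc_prep <- function() fixture("acc_prep", function() {
  ch <- generate_cohort(cohort_config(n_patients = 60, n_genes = 2000,
                                      seed = 101))
  ch <- generate_sentinels(ch, n_sentinels = 8, n_batches = 8, seed = 102)
  prepare_training_data(ch, n_replicates = 100L)
})

acc_lopo <- function() fixture("acc_lopo", function() {
  prep <- acc_prep()
  run_lopo(prep$counts, prep$expr, prep$labels, prep$patient_map,
           prep$frozen, prep$noise, n_draws = 6L, inner_k = 3L, seed = 103)
})
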