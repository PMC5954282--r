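toy_patients <- function(n, seed = 1) {
  data.frame(patient_id = sprintf("p%03d", 1:n),
             label = rep_len(c("UIP", "non-UIP"), n))
}

test_that("fold plans keep patients whole and are deterministic", {
  pats <- toy_patients(90)
  lopo <- make_fold_plan(pats, "lopo")
  expect_equal(length(lopo$folds), 90)
  held <- vapply(lopo$folds, function(f) f$held_out, character(1))
  expect_setequal(held, pats$patient_id)
  for (f in lopo$folds)
    expect_length(intersect(f$held_out, f$train), 0)

  k5 <- make_fold_plan(pats, 5, seed = 2)
  sizes <- vapply(k5$folds, function(f) length(f$held_out), integer(1))
  expect_true(all(sizes == 18))
  expect_setequal(unlist(lapply(k5$folds, `[[`, "held_out")),
                  pats$patient_id)
  k5b <- make_fold_plan(pats, 5, seed = 2)
  expect_identical(k5, k5b)
  expect_false(identical(k5, make_fold_plan(pats, 5, seed = 3)))
})

test_that("penalized logistic separates a separable toy and shrinks to intercept", {
  set.seed(101)
  n <- 60
  y <- rep(c("UIP", "non-UIP"), each = n / 2)
  expr <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n)))
  expr[1, y == "UIP"] <- expr[1, y == "UIP"] + 4
  expr[2, y == "UIP"] <- expr[2, y == "UIP"] - 4
  mod <- train_penalized_logistic(expr, y, lambda = 0.01, mixing = 0.5)
  sc <- score_samples(mod, expr)
  expect_equal(roc_auc(sc, y == "UIP")$auc, 1.0)

  big <- train_penalized_logistic(expr, y, lambda = 50, mixing = 0.5)
  expect_length(big$genes, 0)
  expect_true(all(score_samples(big, expr) == big$intercept))

  expect_error(train_penalized_logistic(expr, rep("UIP", n), 0.1), "classes")
})

test_that("solutions match a full-gradient proximal oracle on 10-gene toys", {
  set.seed(102)
  n <- 50
  x <- matrix(rnorm(n * 10), n, 10)
  y <- as.integer(x[, 1] - x[, 2] + rnorm(n) > 0)
  expr <- t(x)
  dimnames(expr) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:n))
  for (pars in list(c(lambda = 0.1, mixing = 0),
                    c(lambda = 0.05, mixing = 0.7),
                    c(lambda = 0.02, mixing = 1))) {
    mod <- train_penalized_logistic(expr, y, pars["lambda"], pars["mixing"],
                                    standardize = FALSE, thresh = 1e-12)
    w <- setNames(numeric(10), rownames(expr))
    w[mod$genes] <- mod$weights
    orc <- prox_elastic_net(x, y, pars["lambda"], pars["mixing"])
    expect_lt(max(abs(w - orc$beta)), 1e-4)
    expect_lt(abs(mod$intercept - orc$intercept), 1e-4)
    ## and the objectives agree even more tightly
    expect_lt(abs(elastic_net_objective(x, y, mod$intercept, unname(w),
                                        pars["lambda"], pars["mixing"]) -
                  elastic_net_objective(x, y, orc$intercept, orc$beta,
                                        pars["lambda"], pars["mixing"])),
              1e-6)
  }
})

test_that("one-standard-error rule picks the most regularized near-optimum", {
  cand <- data.frame(lambda = c(0.01, 0.05, 0.25), mixing = 0.5)
  ## hand-evaluated: band is min + SE = 0.22, so candidates 1 and 2 qualify
  ## and the larger-lambda second one wins; the third (0.30) does not
  sel <- select_one_se(cand, mean_loss = c(0.20, 0.21, 0.30),
                       se_loss = c(0.02, 0.02, 0.02))
  expect_equal(sel, 2L)
  expect_equal(select_one_se(cand[1, ], 0.2, 0.02), 1L)

  prep <- small_prep()
  t1 <- tune_nested(prep$expr, prep$sample_labels, prep$patient_map,
                    n_draws = 4, inner_k = 3, seed = 9)
  t2 <- tune_nested(prep$expr, prep$sample_labels, prep$patient_map,
                    n_draws = 4, inner_k = 3, seed = 9)
  expect_identical(t1, t2)
  expect_error(tune_nested(prep$expr, prep$sample_labels, prep$patient_map,
                           n_draws = 1), "n_draws")
})

test_that("scores are linear predictors with exact gene alignment", {
  mod <- structure(list(genes = c("gA", "gB"),
                        weights = c(gA = 1, gB = -1), intercept = 0,
                        lambda = 0.1, mixing = 0.5, positive_class = "UIP"),
                   class = "trained_classifier")
  expr <- matrix(c(2, 1), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  expect_equal(unname(score_samples(mod, expr)), 1)
  ## linearity: doubling weights doubles centered scores
  mod2 <- mod; mod2$weights <- mod$weights * 2
  expr2 <- matrix(rnorm(20), 2, 10,
                  dimnames = list(c("gA", "gB"), sprintf("s%d", 1:10)))
  s1 <- score_samples(mod, expr2); s2 <- score_samples(mod2, expr2)
  expect_equal(s2 - mean(s2), 2 * (s1 - mean(s1)), tolerance = 1e-12)
  expect_error(score_samples(mod, expr2[1, , drop = FALSE]), "gB")
})

test_that("ensemble scoring averages, is symmetric, and validates weights", {
  a <- c(s1 = 1, s2 = 5); b <- c(s1 = 3, s2 = 1)
  expect_equal(ensemble_score(list(a, b), c(0.5, 0.5)),
               c(s1 = 2, s2 = 3))
  expect_equal(ensemble_score(list(a), 1), a)
  expect_equal(ensemble_score(list(a, b), c(0.3, 0.7)),
               ensemble_score(list(b, a), c(0.7, 0.3)))
  expect_error(ensemble_score(list(a, b), c(0.5, 0.6)), "sum to 1")
  expect_error(ensemble_score(list(a, b[1])), "identical")
  ## supplied training statistics standardize each component
  expect_equal(ensemble_score(list(a, b), c(0.5, 0.5),
                              centers = c(3, 2), scales = c(2, 1)),
               c(s1 = (1 - 3) / 2 * 0.5 + (3 - 2) * 0.5,
                 s2 = (5 - 3) / 2 * 0.5 + (1 - 2) * 0.5))
})

test_that("tuned sparse models recover planted informative genes", {
  ch <- generate_cohort(cohort_config(n_patients = 30, n_genes = 600,
                                      seed = 111))
  ch <- generate_sentinels(ch, 4, 4, seed = 112)
  prep <- prepare_training_data(ch, n_replicates = 2L)
  tuned <- tune_nested(prep$expr, prep$sample_labels, prep$patient_map,
                       n_draws = 6, inner_k = 3, seed = 113)
  mod <- train_penalized_logistic(prep$expr, prep$sample_labels,
                                  tuned$lambda, tuned$mixing)
  inf <- ch$truth$genes$gene_id[ch$truth$genes$informative]
  expect_gt(length(mod$genes), 3)
  expect_gte(mean(mod$genes %in% inf), 0.8)
})

test_that("classifier JSON round-trips with its locked boundary", {
  mod <- structure(list(genes = c("gA", "gB"),
                        weights = c(gA = 0.5, gB = -0.25), intercept = 1.25,
                        lambda = 0.03, mixing = 0.8, positive_class = "UIP"),
                   class = "trained_classifier")
  path <- tempfile(fileext = ".json")
  write_classifier(mod, path, boundary = 0.87)
  back <- read_classifier(path)
  expect_equal(back$weights, mod$weights)
  expect_equal(back$intercept, mod$intercept)
  expect_equal(attr(back, "boundary"), 0.87)
  expr <- matrix(rnorm(10), 2, 5,
                 dimnames = list(c("gA", "gB"), sprintf("s%d", 1:5)))
  expect_equal(score_samples(back, expr), score_samples(mod, expr))
})
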