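test_that("cohort generation is deterministic and structurally sound", {
  cfg <- cohort_config(n_patients = 12, n_genes = 200, frac_uip = 0.59,
                       seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sample_meta, b$sample_meta)
  expect_identical(a$lobe_diagnoses, b$lobe_diagnoses)

  meta <- a$sample_meta
  expect_setequal(colnames(a$counts), meta$sample_id)
  expect_false(anyDuplicated(meta$sample_id) > 0)
  expect_true(all(a$counts >= 0))
  expect_true(all(a$counts == round(a$counts)))
  ## each biopsy belongs to exactly one patient
  expect_true(all(table(meta$sample_id) == 1))
})

test_that("sample totals respect the per-patient range", {
  ch <- generate_cohort(cohort_config(n_patients = 90, n_genes = 50,
                                      samples_per_patient_range = c(3, 5),
                                      seed = 3))
  n <- sum(ch$sample_meta$role == "biopsy")
  expect_gte(n, 270)
  expect_lte(n, 450)
  per_pat <- table(ch$sample_meta$patient_id)
  expect_true(all(per_pat >= 3 & per_pat <= 5))
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(samples_per_patient_range = c(2, 7)),
               "samples_per_patient_range")
  expect_error(cohort_config(frac_uip = 1.2), "frac_uip")
  expect_error(cohort_config(batch_sd = -1), "batch_sd")
  expect_error(cohort_config(dispersion_params = c(0, 1)),
               "dispersion_params")
  st <- default_nonuip_subtypes()
  st$weight <- st$weight * 2
  expect_error(cohort_config(nonuip_subtypes = st), "sum to 1")
})

test_that("sentinels replicate each source in every batch", {
  ch <- small_cohort()
  n_biopsy <- sum(ch$sample_meta$role == "biopsy")
  ch8 <- generate_sentinels(
    generate_cohort(cohort_config(n_patients = 6, n_genes = 100, seed = 2)),
    n_sentinels = 8, n_batches = 8, seed = 4)
  sent <- ch8$sample_meta[ch8$sample_meta$role == "sentinel", ]
  expect_equal(nrow(sent), 64)
  expect_equal(length(unique(sent$patient_id)), 8)
  expect_true(all(table(sent$patient_id, sent$batch) == 1))

  ## determinism and the unidentifiable-design guard
  ch8b <- generate_sentinels(
    generate_cohort(cohort_config(n_patients = 6, n_genes = 100, seed = 2)),
    n_sentinels = 8, n_batches = 8, seed = 4)
  expect_identical(ch8$counts, ch8b$counts)
  expect_error(generate_sentinels(ch, n_batches = 1), "n_batches")
  expect_equal(sum(ch$sample_meta$role == "biopsy"), n_biopsy)
})

test_that("zero batch SD leaves no batch signal in sentinel variance components", {
  ch <- generate_cohort(cohort_config(n_patients = 4, n_genes = 300,
                                      batch_sd = 0, seed = 9))
  ch <- generate_sentinels(ch, n_sentinels = 6, n_batches = 6, seed = 10)
  frozen <- freeze_normalization(
    ch$counts[, ch$sample_meta$sample_id[ch$sample_meta$role == "biopsy"]])
  sent <- ch$sample_meta[ch$sample_meta$role == "sentinel", ]
  expr <- apply_vst(ch$counts[, sent$sample_id], frozen)
  mods <- fit_gene_batch_model(expr, data.frame(sample_id = sent$sample_id,
                                                source = sent$patient_id,
                                                batch = sent$batch))
  expect_lt(median(mods$sigma2_batch), 0.01)
})

test_that("in-vitro pools mix patient latents and count fresh noise", {
  ch <- generate_cohort(cohort_config(n_patients = 8, n_genes = 150,
                                      samples_per_patient_range = c(1, 3),
                                      batch_sd = 0, seed = 12))
  pats <- ch$truth$patients$patient_id[1:3]
  pooled <- generate_invitro_pools(ch, pats, seed = 13)
  meta <- pooled$sample_meta
  expect_equal(sum(meta$role == "pool"), 3)
  expect_error(generate_invitro_pools(ch, "nope"), "unknown")

  ## a single-sample patient's pool latent equals that sample's latent
  ## (batch_sd = 0 so no new batch term intervenes)
  one <- ch$sample_meta$patient_id[
    ch$sample_meta$patient_id %in%
      names(which(table(ch$sample_meta$patient_id) == 1))][1]
  if (!is.na(one)) {
    p2 <- generate_invitro_pools(ch, one, seed = 14)
    s_col <- ch$sample_meta$sample_id[ch$sample_meta$patient_id == one]
    expect_equal(p2$latent[, paste0("pool_", one)],
                 unname(ch$latent[, s_col]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("patient label rules cover the whole diagnosis vocabulary", {
  expect_equal(assign_patient_label(c(lower = "Classic UIP",
                                      upper = "Nonspecific interstitial pneumonia")),
               "UIP")
  expect_equal(assign_patient_label(c(lower = "Organizing pneumonia",
                                      upper = "non-diagnostic")),
               "non-UIP")
  expect_equal(assign_patient_label(c(lower = "CIF-NOC",
                                      upper = "non-diagnostic")),
               "unlabelable")
  expect_error(assign_patient_label(character(0)), "diagnosis")

  ## total function: every 1- and 2-lobe combination maps to exactly one
  ## of the three outcomes, and UIP dominates any mixture
  vocab <- c("Classic UIP", "Difficult UIP", "Favor UIP",
             "Sarcoidosis", "Hypersensitivity pneumonitis",
             "CIF-NOC", "non-diagnostic")
  uip <- vocab[1:3]
  for (a in vocab) for (b in vocab) {
    out <- assign_patient_label(c(a, b))
    expect_true(out %in% c("UIP", "non-UIP", "unlabelable"))
    if (a %in% uip || b %in% uip) expect_equal(out, "UIP")
  }
})

test_that("discordant-lobe patients still resolve to UIP", {
  ch <- generate_cohort(cohort_config(n_patients = 30, n_genes = 60,
                                      discordant_lobe_rate = 0.2, seed = 21))
  disc <- ch$truth$patients$patient_id[ch$truth$patients$discordant]
  expect_gt(length(disc), 0)
  labs <- cohort_patient_labels(ch)
  expect_true(all(labs[disc] == "UIP"))
  ## and their lobe sets really do conflict
  for (p in disc) {
    dx <- ch$lobe_diagnoses$diagnosis[ch$lobe_diagnoses$patient_id == p]
    expect_true(any(dx %in% c("Classic UIP", "Difficult UIP", "Favor UIP")))
    expect_true(any(!dx %in% c("Classic UIP", "Difficult UIP", "Favor UIP")))
  }
})

test_that("unlabelable patients are excluded from training artifacts", {
  ch <- small_cohort()
  p_drop <- ch$truth$patients$patient_id[1]
  ch$lobe_diagnoses$diagnosis[ch$lobe_diagnoses$patient_id == p_drop] <-
    "non-diagnostic"
  prep <- prepare_training_data(ch, n_replicates = 2L)
  expect_false(p_drop %in% names(prep$labels))
  expect_false(p_drop %in% prep$patient_map)
})

test_that("null-effect count marginals follow the dispersion trend", {
  cfg <- cohort_config(n_patients = 100, n_genes = 300,
                       samples_per_patient_range = c(5, 5),
                       frac_informative_genes = 0, batch_sd = 0,
                       lobe_effect_sd = 0, patient_effect_sd = 0,
                       library_size_range = c(1e6, 1e6),
                       dispersion_params = c(alpha_t = 0.05, alpha_e = 2),
                       seed = 31)
  ch <- generate_cohort(cfg)
  K <- ch$counts
  mu <- rowMeans(K)
  v <- apply(K, 1, var)
  d <- (v - mu) / mu^2
  hi <- mu > 200
  expect_gt(sum(hi), 30)
  ## median empirical dispersion of high-count genes near alpha_t
  expect_lt(abs(median(d[hi]) - 0.05), 0.02)
  ## low-count genes show clear extra-Poisson inflation toward alpha_e/mu
  lo <- mu > 5 & mu < 50
  expect_gt(median((v / mu)[lo]), 1.2)
})

test_that("with no informative genes labels are independent of expression", {
  ## a true expression-null needs the subtype shifts silenced too: non-UIP
  ## subtypes are molecularly distinct by design even without informative
  ## class genes
  st0 <- default_nonuip_subtypes()
  st0$shift_scale <- 0
  cfg <- cohort_config(n_patients = 60, n_genes = 300,
                       frac_informative_genes = 0, batch_sd = 0,
                       nonuip_subtypes = st0, seed = 41)
  ch <- generate_cohort(cfg)
  ch <- generate_sentinels(ch, 4, 4, seed = 42)
  prep <- prepare_training_data(ch, n_replicates = 2L)
  plan <- make_fold_plan(data.frame(patient_id = names(prep$labels),
                                    label = prep$labels), 5, seed = 43)
  ## patient-level held-out mean scores: within-patient samples are
  ## correlated, so samples are not independent units under the null
  sc <- numeric(0)
  for (f in plan$folds) {
    tr <- prep$patient_map %in% f$train
    mod <- train_penalized_logistic(prep$expr[, tr],
                                    prep$sample_labels[tr], 0.05, 0.5)
    s <- score_samples(mod, prep$expr[, !tr, drop = FALSE])
    sc <- c(sc, tapply(s, prep$patient_map[!tr], mean))
  }
  auc <- roc_auc(sc, prep$labels[names(sc)])$auc
  expect_gt(auc, 0.25)
  expect_lt(auc, 0.75)
})

test_that("cohort subsetting keeps consistent metadata", {
  ch <- small_cohort()
  pats <- ch$truth$patients$patient_id[1:5]
  sub <- subset_cohort(ch, pats)
  expect_setequal(unique(sub$sample_meta$patient_id[sub$sample_meta$role == "biopsy"]),
                  pats)
  expect_setequal(colnames(sub$counts), sub$sample_meta$sample_id)
  expect_true(all(sub$truth$patients$patient_id %in% pats))
})

test_that("counts round-trip through TSV", {
  K <- random_counts(20, 5, seed = 51)
  path <- tempfile(fileext = ".tsv")
  write_counts_tsv(K, path)
  expect_identical(read_counts_tsv(path), K)
})
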