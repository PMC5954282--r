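#' Default non-UIP subtype mix
#'
#' Named table of non-UIP interstitial lung disease subtypes with prevalence
#' weights reflecting the mix commonly seen in a development cohort
#' (respiratory bronchiolitis and organizing pneumonia most frequent) and a
#' log2-scale SD for each subtype's molecular mean shift.
#'
#' @return data.frame with columns `name`, `weight` (sums to 1),
#'   `shift_scale`.
#' @export
default_nonuip_subtypes <- function() {
  d <- data.frame(
    name = c("Respiratory bronchiolitis", "Organizing pneumonia",
             "Hypersensitivity pneumonitis", "Sarcoidosis",
             "Nonspecific interstitial pneumonia", "Bronchiolitis",
             "Emphysema", "Other non-UIP"),
    weight = c(7, 7, 4, 4, 3, 3, 3, 6),
    shift_scale = 0.8,
    stringsAsFactors = FALSE)
  d$weight <- d$weight / sum(d$weight)
  d
}

#' Configure a synthetic biopsy cohort
#'
#' Defines the study conditions for the synthetic cohort generator: a
#' multi-sample-per-patient transbronchial-biopsy RNA-seq study with binary
#' UIP / non-UIP patient labels, heterogeneous non-UIP subtypes, within-
#' patient lobe heterogeneity, processing-batch effects, and negative-
#' binomial counting noise. Defaults emulate a 90-patient training cohort
#' with 3-5 biopsies per patient, 59% UIP prevalence, and 8 processing
#' batches.
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient_range Integer interval within 1..5.
#' @param n_genes Number of genes.
#' @param frac_uip Proportion of UIP patients.
#' @param nonuip_subtypes data.frame(name, weight, shift_scale); weights must
#'   sum to 1.
#' @param frac_informative_genes Proportion of genes carrying a UIP class
#'   effect.
#' @param effect_size_sd log2-scale SD of per-gene class effects.
#' @param lobe_effect_sd log2-scale SD of within-patient lobe deviations.
#' @param patient_effect_sd log2-scale SD of per-patient baseline deviations.
#' @param batch_sd log2-scale SD of batch random effects.
#' @param n_batches Number of processing batches.
#' @param library_size_range Interval of expected total counts per sample.
#' @param dispersion_params c(alpha_t, alpha_e) for the negative-binomial
#'   dispersion trend alpha(mu) = alpha_t + alpha_e / mu; alpha_t > 0,
#'   alpha_e >= 0. This is technical (counting and library-preparation)
#'   noise only: biological variation enters through the latent patient,
#'   lobe, subtype, and batch effects, so the default is on the
#'   technical-replicate scale rather than the larger biological-replicate
#'   dispersion scale.
#' @param discordant_lobe_rate Proportion of patients whose lobes carry
#'   conflicting (UIP and non-UIP) diagnoses.
#' @param nondiagnostic_rate Per-sample rate of non-diagnostic pathology;
#'   such samples carry no sample-level label but inherit the patient label.
#' @param seed Integer RNG seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 90L,
                          samples_per_patient_range = c(3L, 5L),
                          n_genes = 2000L,
                          frac_uip = 0.59,
                          nonuip_subtypes = default_nonuip_subtypes(),
                          frac_informative_genes = 0.10,
                          effect_size_sd = 1.0,
                          lobe_effect_sd = 0.30,
                          patient_effect_sd = 0.30,
                          batch_sd = 0.20,
                          n_batches = 8L,
                          library_size_range = c(5e5, 1.5e6),
                          dispersion_params = c(alpha_t = 0.01, alpha_e = 1),
                          discordant_lobe_rate = 3 / 90,
                          nondiagnostic_rate = 0.05,
                          seed = 1L) {
  fail <- function(field, msg) stop(sprintf("invalid cohort config: `%s` %s",
                                            field, msg), call. = FALSE)
  if (!(length(n_patients) == 1 && n_patients >= 1)) fail("n_patients", "must be >= 1")
  r <- as.integer(samples_per_patient_range)
  if (length(r) != 2 || r[1] > r[2] || r[1] < 1 || r[2] > 5)
    fail("samples_per_patient_range", "must be an interval within 1..5")
  if (!(length(n_genes) == 1 && n_genes >= 10)) fail("n_genes", "must be >= 10")
  if (!(frac_uip >= 0 && frac_uip <= 1)) fail("frac_uip", "must be in [0,1]")
  st <- nonuip_subtypes
  if (!is.data.frame(st) || !all(c("name", "weight", "shift_scale") %in% names(st)))
    fail("nonuip_subtypes", "must have columns name, weight, shift_scale")
  if (abs(sum(st$weight) - 1) > 1e-8)
    fail("nonuip_subtypes", "prevalence weights must sum to 1")
  if (!(frac_informative_genes >= 0 && frac_informative_genes <= 1))
    fail("frac_informative_genes", "must be in [0,1]")
  for (f in c("effect_size_sd", "lobe_effect_sd", "patient_effect_sd", "batch_sd",
              "discordant_lobe_rate", "nondiagnostic_rate")) {
    v <- get(f)
    if (!(length(v) == 1 && is.finite(v) && v >= 0)) fail(f, "must be >= 0")
  }
  if (discordant_lobe_rate > 1) fail("discordant_lobe_rate", "must be <= 1")
  if (nondiagnostic_rate > 1) fail("nondiagnostic_rate", "must be <= 1")
  if (!(n_batches >= 1)) fail("n_batches", "must be >= 1")
  ls <- library_size_range
  if (length(ls) != 2 || any(ls <= 0) || ls[1] > ls[2])
    fail("library_size_range", "must be a positive interval")
  dp <- dispersion_params
  if (length(dp) != 2 || dp[1] <= 0 || dp[2] < 0)
    fail("dispersion_params", "needs alpha_t > 0 and alpha_e >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 samples_per_patient_range = r,
                 n_genes = as.integer(n_genes), frac_uip = frac_uip,
                 nonuip_subtypes = st,
                 frac_informative_genes = frac_informative_genes,
                 effect_size_sd = effect_size_sd,
                 lobe_effect_sd = lobe_effect_sd,
                 patient_effect_sd = patient_effect_sd,
                 batch_sd = batch_sd, n_batches = as.integer(n_batches),
                 library_size_range = as.numeric(ls),
                 dispersion_params = c(alpha_t = unname(dp[1]),
                                       alpha_e = unname(dp[2])),
                 discordant_lobe_rate = discordant_lobe_rate,
                 nondiagnostic_rate = nondiagnostic_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

uip_subtype_vocab <- c("Classic UIP", "Difficult UIP", "Favor UIP")

## Draw NB counts from latent log2 expression (genes x samples) at given
## expected library sizes. Dispersion follows the configured trend
## alpha(mu) = alpha_t + alpha_e / mu evaluated at the expected count.
.counts_from_latent <- function(latent, lib_sizes, dp) {
  m <- nrow(latent); n <- ncol(latent)
  K <- matrix(0L, m, n, dimnames = dimnames(latent))
  for (i in seq_len(n)) {
    q <- 2^latent[, i]
    mu <- lib_sizes[i] * q / sum(q)
    alpha <- dp["alpha_t"] + dp["alpha_e"] / pmax(mu, 1e-8)
    K[, i] <- stats::rnbinom(m, mu = mu, size = 1 / alpha)
  }
  K
}

#' Generate a synthetic multi-sample-per-patient cohort
#'
#' Latent log2 expression of each biopsy is the sum of a per-gene baseline,
#' a UIP class effect on the informative genes, a subtype shift on a
#' subtype-specific disjoint gene set (non-UIP patients), per-patient and
#' per-(patient, lobe) random deviations, and a batch random effect. Counts
#' are negative-binomial with mean proportional to 2^latent at the sample's
#' library size and dispersion from the configured trend. Lobe-level
#' pathology diagnoses, patient truth, gene truth, and a gene annotation
#' table are returned alongside the counts. Deterministic given
#' `config$seed`.
#'
#' @param config A `cohort_config`.
#' @return Object of class `simulated_cohort`: list with `counts` (genes x
#'   samples integer matrix), `sample_meta` (sample_id, patient_id, lobe,
#'   batch, role, nondiagnostic), `lobe_diagnoses` (patient_id, lobe,
#'   diagnosis), `annotation` (gene_id, biotype, in_target_panel), `truth`
#'   (list: `genes` with informative flag and effect size, `patients` with
#'   class and subtype), plus internal latent state reused by
#'   [generate_sentinels()] and [generate_invitro_pools()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  with_seed(cf$seed, {
    m <- cf$n_genes
    genes <- sprintf("g%05d", seq_len(m))
    baseline <- stats::rnorm(m, mean = 5, sd = 2)

    ## annotation: planted-signal genes are kept protein_coding and on-panel
    biotype <- sample(c("protein_coding", "pseudogene", "rRNA", "TR_IG_exon"),
                      m, replace = TRUE, prob = c(0.92, 0.05, 0.02, 0.01))
    in_panel <- stats::runif(m) < 0.95

    n_inf <- round(cf$frac_informative_genes * m)
    inf_idx <- if (n_inf > 0) sample.int(m, n_inf) else integer(0)
    class_effect <- numeric(m)
    class_effect[inf_idx] <- stats::rnorm(n_inf, 0, cf$effect_size_sd)

    ## disjoint subtype gene sets drawn from the non-informative pool
    st <- cf$nonuip_subtypes
    pool <- setdiff(seq_len(m), inf_idx)
    k_sub <- min(round(0.05 * m), floor(length(pool) / max(nrow(st), 1)))
    subtype_shift <- matrix(0, m, nrow(st), dimnames = list(genes, st$name))
    for (s in seq_len(nrow(st))) {
      idx <- sample(pool, k_sub)
      pool <- setdiff(pool, idx)
      subtype_shift[idx, s] <- stats::rnorm(k_sub, 0, st$shift_scale[s])
    }
    signal_idx <- union(inf_idx, which(rowSums(subtype_shift != 0) > 0))
    biotype[signal_idx] <- "protein_coding"
    in_panel[signal_idx] <- TRUE

    ## patients
    P <- cf$n_patients
    patients <- sprintf("p%03d", seq_len(P))
    n_uip <- round(cf$frac_uip * P)
    cls <- sample(c(rep("UIP", n_uip), rep("non-UIP", P - n_uip)))
    subtype <- ifelse(cls == "UIP", NA_character_,
                      sample(st$name, P, replace = TRUE, prob = st$weight))
    n_samp <- sample(seq(cf$samples_per_patient_range[1],
                         cf$samples_per_patient_range[2]),
                     P, replace = TRUE)

    patient_eff <- matrix(stats::rnorm(m * P, 0, cf$patient_effect_sd), m, P,
                          dimnames = list(genes, patients))
    batch_eff <- matrix(stats::rnorm(m * cf$n_batches, 0, cf$batch_sd), m,
                        cf$n_batches)

    ## biopsy samples: typical lobe pattern alternates lower/upper
    lobe_pattern <- c("lower", "upper", "lower", "upper", "lower")
    sample_id <- character(0); s_patient <- character(0)
    s_lobe <- character(0); s_batch <- integer(0)
    n_total <- sum(n_samp)
    latent <- matrix(0, m, n_total)
    col <- 0L
    lobe_eff_cache <- list()
    for (p in seq_len(P)) {
      lobes <- lobe_pattern[seq_len(n_samp[p])]
      for (lb in unique(lobes))
        lobe_eff_cache[[paste(patients[p], lb)]] <-
          stats::rnorm(m, 0, cf$lobe_effect_sd)
      for (j in seq_len(n_samp[p])) {
        col <- col + 1L
        b <- sample.int(cf$n_batches, 1)
        lat <- baseline + patient_eff[, p] +
          lobe_eff_cache[[paste(patients[p], lobes[j])]] + batch_eff[, b]
        if (cls[p] == "UIP") lat <- lat + class_effect
        else lat <- lat + subtype_shift[, subtype[p]]
        latent[, col] <- lat
        sample_id <- c(sample_id, sprintf("s%04d", col))
        s_patient <- c(s_patient, patients[p])
        s_lobe <- c(s_lobe, lobes[j]); s_batch <- c(s_batch, b)
      }
    }
    dimnames(latent) <- list(genes, sample_id)
    lib <- stats::runif(n_total, cf$library_size_range[1],
                        cf$library_size_range[2])
    counts <- .counts_from_latent(latent, lib, cf$dispersion_params)

    nondx <- stats::runif(n_total) < cf$nondiagnostic_rate

    ## lobe-level diagnoses; a subset of UIP patients is lobe-discordant
    n_disc <- round(cf$discordant_lobe_rate * P)
    disc <- rep(FALSE, P)
    uip_multi <- which(cls == "UIP" & n_samp >= 2)
    if (n_disc > 0 && length(uip_multi))
      disc[sample(uip_multi, min(n_disc, length(uip_multi)))] <- TRUE
    ld <- do.call(rbind, lapply(seq_len(P), function(p) {
      lobes <- unique(lobe_pattern[seq_len(n_samp[p])])
      dx <- if (cls[p] == "UIP")
        sample(uip_subtype_vocab, length(lobes), replace = TRUE)
      else rep(subtype[p], length(lobes))
      if (disc[p] && length(lobes) >= 2)
        dx[length(lobes)] <- sample(st$name, 1)
      data.frame(patient_id = patients[p], lobe = lobes, diagnosis = dx,
                 stringsAsFactors = FALSE)
    }))

    structure(list(
      counts = counts,
      sample_meta = data.frame(sample_id = sample_id, patient_id = s_patient,
                               lobe = s_lobe, batch = s_batch, role = "biopsy",
                               nondiagnostic = nondx, stringsAsFactors = FALSE),
      lobe_diagnoses = ld,
      annotation = data.frame(gene_id = genes, biotype = biotype,
                              in_target_panel = in_panel,
                              stringsAsFactors = FALSE),
      truth = list(
        genes = data.frame(gene_id = genes,
                           informative = seq_len(m) %in% inf_idx,
                           effect_size = class_effect,
                           stringsAsFactors = FALSE),
        patients = data.frame(patient_id = patients, class = cls,
                              subtype = subtype, discordant = disc,
                              stringsAsFactors = FALSE)),
      latent = latent, baseline = baseline, batch_effects = batch_eff,
      config = cf), class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  tab <- table(x$sample_meta$role)
  cat(sprintf("simulated cohort: %d genes x %d samples (%s); %d patients\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$truth$patients)))
  invisible(x)
}

#' Append sentinel replicate samples
#'
#' Sentinels are fixed biological sources re-processed in every batch: each
#' of `n_sentinels` sources gets one sample per batch, sharing the source's
#' latent expression but receiving that batch's random effect and fresh
#' counting noise. They expose technical batch variability without any
#' biological signal of interest.
#'
#' @param cohort A `simulated_cohort`.
#' @param n_sentinels Number of biological sentinel sources (>= 1).
#' @param n_batches Number of batches each source is replicated in (>= 2;
#'   fewer leaves batch variance unidentifiable).
#' @param seed RNG seed for sentinel draws.
#' @return The cohort with `n_sentinels * n_batches` sentinel samples
#'   appended (role = "sentinel"; patient_id names the sentinel source).
#' @export
generate_sentinels <- function(cohort, n_sentinels = 8L, n_batches = 8L,
                               seed = 1L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (n_sentinels < 1) stop("n_sentinels must be >= 1")
  if (n_batches < 2)
    stop("n_batches must be >= 2: batch variance components are unidentifiable from a single batch")
  cf <- cohort$config
  with_seed(seed, {
    m <- nrow(cohort$counts)
    batch_eff <- cohort$batch_effects
    if (n_batches > ncol(batch_eff))
      batch_eff <- cbind(batch_eff,
                         matrix(stats::rnorm(m * (n_batches - ncol(batch_eff)),
                                             0, cf$batch_sd), m))
    src_latent <- vapply(seq_len(n_sentinels), function(s)
      cohort$baseline + stats::rnorm(m, 0, cf$patient_effect_sd),
      numeric(m))
    ids <- character(0); src <- character(0); bat <- integer(0)
    latent <- matrix(0, m, n_sentinels * n_batches)
    col <- 0L
    for (s in seq_len(n_sentinels)) for (b in seq_len(n_batches)) {
      col <- col + 1L
      latent[, col] <- src_latent[, s] + batch_eff[, b]
      ids <- c(ids, sprintf("sent%02d_b%02d", s, b))
      src <- c(src, sprintf("sentinel%02d", s)); bat <- c(bat, b)
    }
    dimnames(latent) <- list(rownames(cohort$counts), ids)
    lib <- stats::runif(col, cf$library_size_range[1], cf$library_size_range[2])
    K <- .counts_from_latent(latent, lib, cf$dispersion_params)
    cohort$counts <- cbind(cohort$counts, K)
    cohort$latent <- cbind(cohort$latent, latent)
    cohort$sample_meta <- rbind(cohort$sample_meta,
      data.frame(sample_id = ids, patient_id = src, lobe = NA_character_,
                 batch = bat, role = "sentinel", nondiagnostic = NA,
                 stringsAsFactors = FALSE))
    cohort
  })
}

#' Append in-vitro pooled samples
#'
#' For each named patient, forms one pooled sample whose latent expression is
#' the equal-weight linear mixture (on the concentration scale) of that
#' patient's biopsy latent profiles, then re-counts it with a fresh library
#' size, batch effect, and counting noise — the wet-lab analogue of in-silico
#' mixing.
#'
#' @param cohort A `simulated_cohort`.
#' @param patient_ids Patients to pool (each must have at least one biopsy).
#' @param seed RNG seed.
#' @return The cohort with one pool sample per patient appended
#'   (role = "pool").
#' @export
generate_invitro_pools <- function(cohort, patient_ids, seed = 1L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  meta <- cohort$sample_meta
  cf <- cohort$config
  unknown <- setdiff(patient_ids,
                     meta$patient_id[meta$role == "biopsy"])
  if (length(unknown))
    stop("unknown patient id(s) or patients without biopsies: ",
         paste(unknown, collapse = ", "))
  with_seed(seed, {
    m <- nrow(cohort$counts)
    latent <- vapply(patient_ids, function(p) {
      cols <- meta$sample_id[meta$patient_id == p & meta$role == "biopsy"]
      log2(rowMeans(2^cohort$latent[, cols, drop = FALSE]))
    }, numeric(m))
    ids <- sprintf("pool_%s", patient_ids)
    colnames(latent) <- ids
    bat <- sample.int(cf$n_batches, length(patient_ids), replace = TRUE)
    latent <- latent + cohort$batch_effects[, bat, drop = FALSE]
    dimnames(latent) <- list(rownames(cohort$counts), ids)
    lib <- stats::runif(length(ids), cf$library_size_range[1],
                        cf$library_size_range[2])
    K <- .counts_from_latent(latent, lib, cf$dispersion_params)
    cohort$counts <- cbind(cohort$counts, K)
    cohort$latent <- cbind(cohort$latent, latent)
    cohort$sample_meta <- rbind(cohort$sample_meta,
      data.frame(sample_id = ids, patient_id = patient_ids,
                 lobe = NA_character_, batch = bat, role = "pool",
                 nondiagnostic = NA, stringsAsFactors = FALSE))
    cohort
  })
}

#' Restrict a cohort to a patient subset
#'
#' Keeps the biopsy samples (and lobe diagnoses, truth rows) of the given
#' patients, and optionally the sentinel samples. Used to split one
#' generated population into a training arm and an independent test arm
#' that share the same gene-level ground truth.
#'
#' @param cohort A `simulated_cohort`.
#' @param patient_ids Patients to keep.
#' @param keep_sentinels Keep sentinel columns (default TRUE).
#' @return A `simulated_cohort` restricted to the subset.
#' @export
subset_cohort <- function(cohort, patient_ids, keep_sentinels = TRUE) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  meta <- cohort$sample_meta
  unknown <- setdiff(patient_ids, meta$patient_id[meta$role == "biopsy"])
  if (length(unknown))
    stop("unknown patient id(s): ", paste(unknown, collapse = ", "))
  keep <- (meta$role == "biopsy" & meta$patient_id %in% patient_ids) |
    (keep_sentinels & meta$role == "sentinel")
  cohort$sample_meta <- meta[keep, ]
  cohort$counts <- cohort$counts[, cohort$sample_meta$sample_id, drop = FALSE]
  cohort$latent <- cohort$latent[, cohort$sample_meta$sample_id, drop = FALSE]
  cohort$lobe_diagnoses <-
    cohort$lobe_diagnoses[cohort$lobe_diagnoses$patient_id %in% patient_ids, ]
  cohort$truth$patients <-
    cohort$truth$patients[cohort$truth$patients$patient_id %in% patient_ids, ]
  cohort
}

#' Assign a patient-level label from lobe diagnoses
#'
#' Aggregation rules: if any lobe carries any UIP subtype (Classic UIP,
#' Difficult UIP, Favor UIP) the patient is "UIP"; otherwise, if any lobe
#' carries a named non-UIP condition the patient is "non-UIP"; when every
#' lobe is non-diagnostic or unclassifiable fibrosis (CIF-NOC) no reference
#' label can be assigned and the patient is "unlabelable" (excluded from
#' training and evaluation).
#'
#' @param lobe_diagnoses Character vector of per-lobe diagnoses (optionally
#'   named by lobe). "non-diagnostic" and "CIF-NOC" are the two
#'   non-assignable values; any other string is a named non-UIP condition.
#' @return One of "UIP", "non-UIP", "unlabelable".
#' @export
assign_patient_label <- function(lobe_diagnoses) {
  dx <- as.character(lobe_diagnoses)
  if (!length(dx) || any(is.na(dx)) || any(!nzchar(dx)))
    stop("at least one non-missing lobe diagnosis is required")
  if (any(dx %in% uip_subtype_vocab)) return("UIP")
  nonassign <- c("non-diagnostic", "CIF-NOC")
  if (any(!dx %in% nonassign)) return("non-UIP")
  "unlabelable"
}

#' Patient labels for a simulated cohort
#'
#' Applies [assign_patient_label()] to each patient's lobe diagnoses.
#'
#' @param cohort A `simulated_cohort`.
#' @return Named character vector of labels, one per patient.
#' @export
cohort_patient_labels <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  split_dx <- split(cohort$lobe_diagnoses$diagnosis,
                    cohort$lobe_diagnoses$patient_id)
  vapply(split_dx, assign_patient_label, character(1))
}
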