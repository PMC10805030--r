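#' Describe one omic layer of a simulated cohort
#'
#' Defines the generative block for a single layer: number of features, how
#' many are causal (shifted between cases and controls), the magnitude of
#' the planted case/control log-abundance shift, the baseline log-abundance
#' distribution across features, sequencing depth for count layers, extra
#' zero-inflation, and the probability that a sample is missing the layer
#' entirely.
#'
#' @param n_features number of features in the layer.
#' @param n_causal number of causal features (`<= n_features`).
#' @param effect_size magnitude of the case-vs-control shift in latent log
#'   abundance for causal features; each causal feature gets a random sign.
#' @param base_log_mean,base_log_sd mean and SD of per-feature baseline log
#'   abundances (drawn once per cohort).
#' @param library_size multinomial depth for count layers; `NA` for
#'   intensity layers (MBL), which emit exponentiated latent values.
#' @param zero_inflation mean per-feature probability that an observed cell
#'   is masked to zero after the count draw.
#' @param zero_inflation_conc concentration of the Beta distribution the
#'   per-feature masking probabilities are drawn from; small values spread
#'   presence fractions widely across features (sparse layers such as VRM),
#'   large values make masking near-uniform.
#' @param missing_layer_prob probability a sample lacks this layer.
#' @param noise_sd SD of per-sample latent log-abundance noise.
#' @param causal_pool `"abundant"` plants causal effects among the top half
#'   of features by baseline abundance (detectable features, mirroring that
#'   selected features in real cohorts are the prevalent ones); `"any"`
#'   draws them uniformly.
#' @return a `layer_design` list.
#' @export
layer_design <- function(n_features, n_causal, effect_size,
                         base_log_mean = 0, base_log_sd = 1.5,
                         library_size = 1e5, zero_inflation = 0,
                         zero_inflation_conc = 10,
                         missing_layer_prob = 0, noise_sd = 0.5,
                         causal_pool = c("abundant", "any")) {
  causal_pool <- match.arg(causal_pool)
  if (n_causal > n_features) {
    abort("n_causal must be <= n_features", class = "polyomics_error_design")
  }
  if (any(c(zero_inflation, missing_layer_prob) < 0) ||
      any(c(zero_inflation, missing_layer_prob) > 1)) {
    abort("probabilities must lie in [0, 1]", class = "polyomics_error_design")
  }
  if (!is.na(library_size) && library_size <= 0) {
    abort("library_size must be positive", class = "polyomics_error_design")
  }
  structure(
    list(
      n_features = as.integer(n_features), n_causal = as.integer(n_causal),
      effect_size = effect_size, base_log_mean = base_log_mean,
      base_log_sd = base_log_sd, library_size = library_size,
      zero_inflation = zero_inflation, zero_inflation_conc = zero_inflation_conc,
      missing_layer_prob = missing_layer_prob, noise_sd = noise_sd,
      causal_pool = causal_pool
    ),
    class = "layer_design"
  )
}

#' Describe a simulated multi-omic longitudinal cohort
#'
#' @param n_participants number of participants.
#' @param n_cases number of IBD cases among them (split CD/UC at the cohort
#'   ratio 65:38).
#' @param n_sites number of study sites.
#' @param weeks integer vector of collection weeks shared by all
#'   participants; each week yields one fecal sample.
#' @param layers named list of [layer_design()] blocks; names become layer
#'   tags and must be among MGN/MTS/VRM/MBL.
#' @param participant_re_sd SD of per-participant, per-feature random
#'   intercepts on the latent log scale (drives within-participant
#'   correlation of repeated samples).
#' @param site_re_sd SD of per-site, per-feature random intercepts.
#' @param site_probs optional site assignment probabilities (length
#'   `n_sites`); default uniform.
#' @param abx_case_prob,abx_control_prob antibiotic-use probability for
#'   cases and controls.
#' @param age_mean,age_sd,age_range age distribution (normal, truncated).
#' @param seed master RNG seed; each layer derives an independent stream.
#' @param keep_latent store the per-sample latent log-abundance matrices in
#'   the truth object (needed for intraclass-correlation checks; off by
#'   default to save memory).
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(n_participants, n_cases, n_sites, weeks, layers,
                              participant_re_sd = 0.5, site_re_sd = 0.25,
                              site_probs = NULL,
                              abx_case_prob = 19 / 103, abx_control_prob = 0,
                              age_mean = 28, age_sd = 17, age_range = c(6, 76),
                              seed = 1, keep_latent = FALSE) {
  if (n_cases > n_participants) {
    abort("n_cases must be <= n_participants", class = "polyomics_error_design")
  }
  if (is.null(names(layers)) || !all(names(layers) %in% OMIC_LAYERS)) {
    abort("layers must be a named list with names among MGN/MTS/VRM/MBL",
          class = "polyomics_error_design")
  }
  if (!is.null(site_probs) && length(site_probs) != n_sites) {
    abort("site_probs must have length n_sites", class = "polyomics_error_design")
  }
  structure(
    list(
      n_participants = as.integer(n_participants), n_cases = as.integer(n_cases),
      n_sites = as.integer(n_sites), weeks = as.integer(weeks), layers = layers,
      participant_re_sd = participant_re_sd, site_re_sd = site_re_sd,
      site_probs = site_probs, abx_case_prob = abx_case_prob,
      abx_control_prob = abx_control_prob, age_mean = age_mean, age_sd = age_sd,
      age_range = age_range, seed = as.integer(seed), keep_latent = keep_latent
    ),
    class = "simulation_design"
  )
}

#' A design emulating the HMP2 IBD cohort's shape
#'
#' Packaged [simulation_design()] approximating the cohort the framework was
#' developed on: 130 participants (103 IBD cases, 27 controls) across 5
#' study sites, ages drawn from Normal(28, 17) truncated to 6-76 years,
#' longitudinal sampling every 4 weeks over one year, and four omic layers
#' with pre-filter feature counts 578 (MGN), 421 (MTS), 239 (VRM) and 596
#' (MBL). Planted effects are strong in the metabolomic and viromic layers,
#' moderate in metatranscriptomics and weak in metagenomics, matching the
#' relative predictive ability the framework is designed to expose. VRM is
#' generated highly sparse (most viruses in few samples) and MBL
#' near-complete (most compounds in most samples), so the layer-specific
#' presence filters have realistic work to do.
#'
#' @param seed master RNG seed.
#' @param ... overrides passed to [simulation_design()].
#' @return a `simulation_design`.
#' @export
hmp2_like_design <- function(seed = 1, ...) {
  simulation_design(
    n_participants = 130, n_cases = 103, n_sites = 5,
    weeks = seq(0L, 48L, by = 4L),
    layers = list(
      MGN = layer_design(578, 14, effect_size = 0.3, base_log_mean = 0,
                         base_log_sd = 2.0, library_size = 1e5,
                         zero_inflation = 0.10, zero_inflation_conc = 5,
                         missing_layer_prob = 0.05),
      MTS = layer_design(421, 22, effect_size = 0.6, base_log_mean = 0,
                         base_log_sd = 1.5, library_size = 1e6,
                         zero_inflation = 0.05, zero_inflation_conc = 5,
                         missing_layer_prob = 0.35),
      VRM = layer_design(239, 6, effect_size = 0.9, base_log_mean = 0,
                         base_log_sd = 3.0, library_size = 1e4,
                         zero_inflation = 0.93, zero_inflation_conc = 0.4,
                         missing_layer_prob = 0.40),
      MBL = layer_design(596, 14, effect_size = 0.5, base_log_mean = 10,
                         base_log_sd = 1.0, library_size = NA,
                         zero_inflation = 0.02, zero_inflation_conc = 25,
                         missing_layer_prob = 0.50)
    ),
    participant_re_sd = 0.5, site_re_sd = 0.25,
    site_probs = c(0.254, 0.254, 0.285, 0.123, 0.085),
    seed = seed, ...
  )
}

# stable per-layer RNG stream offsets so adding/removing one layer never
# perturbs another layer's draws
layer_seed <- function(master, layer) {
  offsets <- c(MGN = 1L, MTS = 2L, VRM = 3L, MBL = 4L)
  as.integer((as.numeric(master) + 7919 * offsets[[layer]]) %% 2147483629)
}

#' Simulate a multi-omic longitudinal cohort with known ground truth
#'
#' Generates per-layer feature tables, per-sample metadata, and a truth
#' object recording the planted signal. The scheme is case-control
#' conditional: diagnosis is assigned to participants first, then each
#' layer's per-participant latent log-abundance profile is baseline +
#' causal shift (cases only) + participant random intercept + site random
#' intercept, with i.i.d. per-sample noise around the participant mean.
#' Count layers exponentiate, normalize, draw multinomial counts at the
#' layer's library size and apply a per-feature zero-inflation mask; the
#' intensity layer emits exponentiated latents. Each (sample, layer) pair
#' is then dropped independently with the layer's missingness probability.
#' Fully deterministic given `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return list with `tables` (named list of [omic_table()]), `metadata`
#'   (cohort metadata tibble) and `truth` (planted causal features and
#'   effects, random intercepts, diagnosis assignment).
#' @export
simulate_cohort <- function(design) {
  if (!inherits(design, "simulation_design")) {
    abort("design must be a simulation_design", class = "polyomics_error_design")
  }
  meta <- simulate_metadata(design)
  participants <- unique(meta[c("participant_id", "diagnosis", "site")])
  case <- ibd_label(participants$diagnosis)

  tables <- list()
  truth_layers <- list()
  for (layer in names(design$layers)) {
    ld <- design$layers[[layer]]
    set.seed(layer_seed(design$seed, layer))
    gen <- simulate_layer(ld, layer, meta, participants, case,
                          design$participant_re_sd, design$site_re_sd,
                          design$keep_latent)
    tables[[layer]] <- gen$table
    truth_layers[[layer]] <- gen$truth
  }
  truth <- list(
    diagnosis = participants,
    layers = truth_layers,
    seed = design$seed
  )
  list(tables = tables, metadata = meta, truth = truth)
}

simulate_metadata <- function(design) {
  set.seed(design$seed)
  n <- design$n_participants
  pid <- sprintf("P%03d", seq_len(n))
  case_idx <- sample.int(n, design$n_cases)
  diagnosis <- rep("nonIBD", n)
  # CD:UC split at the cohort ratio 65:38
  diagnosis[case_idx] <- sample(c("CD", "UC"), design$n_cases, replace = TRUE,
                                prob = c(65, 38))
  probs <- design$site_probs %||% rep(1 / design$n_sites, design$n_sites)
  site <- sample(sprintf("site%d", seq_len(design$n_sites)), n,
                 replace = TRUE, prob = probs)
  age <- rnorm_trunc(n, design$age_mean, design$age_sd, design$age_range)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  race <- sample(c("White", "Black or African American", "More than one race",
                   "Others"), n, replace = TRUE, prob = c(0.846, 0.077, 0.038, 0.039))
  abx <- ifelse(diagnosis == "nonIBD",
                rbinom(n, 1, design$abx_control_prob),
                rbinom(n, 1, design$abx_case_prob)) == 1

  per_part <- tibble::tibble(
    participant_id = pid, diagnosis = diagnosis, age = age, sex = sex,
    race = race, antibiotic_use = abx, site = site
  )
  meta <- tidyr::expand_grid(per_part, week = design$weeks)
  meta <- dplyr::mutate(meta,
                        sample_id = sprintf("%s_W%02d", .data$participant_id, .data$week),
                        .before = 1)
  as_cohort_metadata(meta)
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

simulate_layer <- function(ld, layer, meta, participants, case,
                           participant_re_sd, site_re_sd, keep_latent) {
  p <- ld$n_features
  n_part <- nrow(participants)
  feat_ids <- sprintf("%s_f%04d", layer, seq_len(p))

  base <- rnorm(p, ld$base_log_mean, ld$base_log_sd)
  zi_prob <- if (ld$zero_inflation > 0) {
    k <- ld$zero_inflation_conc
    stats::rbeta(p, k * ld$zero_inflation, k * (1 - ld$zero_inflation))
  } else {
    numeric(p)
  }
  # causal effects are planted on detectable features: the abundant half
  # (when causal_pool = "abundant"), preferring low-dropout features, as
  # the discriminative features of real cohorts are the prevalent ones
  pool <- if (ld$causal_pool == "abundant" && p > 1) {
    top <- order(base, decreasing = TRUE)[seq_len(max(ld$n_causal, ceiling(p / 2)))]
    top[order(zi_prob[top])][seq_len(min(length(top), max(ld$n_causal, 3 * ld$n_causal)))]
  } else {
    seq_len(p)
  }
  causal <- sort(sample(pool, ld$n_causal))
  delta <- numeric(p)
  delta[causal] <- ld$effect_size * sample(c(-1, 1), ld$n_causal, replace = TRUE)

  part_re <- matrix(rnorm(n_part * p, 0, participant_re_sd), n_part, p,
                    dimnames = list(participants$participant_id, feat_ids))
  sites <- sort(unique(participants$site))
  site_re <- matrix(rnorm(length(sites) * p, 0, site_re_sd), length(sites), p,
                    dimnames = list(sites, feat_ids))

  idx_part <- match(meta$participant_id, participants$participant_id)
  idx_site <- match(meta$site, sites)
  n_samp <- nrow(meta)

  latent <- matrix(rep(base, each = n_samp), n_samp, p) +
    matrix(rep(delta, each = n_samp), n_samp, p) * case[idx_part] +
    part_re[idx_part, , drop = FALSE] +
    site_re[idx_site, , drop = FALSE] +
    matrix(rnorm(n_samp * p, 0, ld$noise_sd), n_samp, p)
  dimnames(latent) <- list(meta$sample_id, feat_ids)

  if (is.na(ld$library_size)) {
    values <- exp(latent)
  } else {
    prob <- exp(latent - apply(latent, 1, max))
    values <- t(apply(prob, 1, function(pr) {
      rmultinom(1, size = ld$library_size, prob = pr)[, 1]
    }))
    dimnames(values) <- dimnames(latent)
  }

  if (ld$zero_inflation > 0) {
    mask <- matrix(rbinom(n_samp * p, 1, rep(zi_prob, each = n_samp)), n_samp, p)
    values <- values * (1 - mask)
  }

  present <- runif(n_samp) >= ld$missing_layer_prob
  values <- values[present, , drop = FALSE]

  truth <- list(
    feature_ids = feat_ids,
    causal = feat_ids[causal],
    delta = setNames(delta[causal], feat_ids[causal]),
    zero_inflation_prob = setNames(zi_prob, feat_ids),
    participant_re = if (keep_latent) part_re else NULL,
    site_re = if (keep_latent) site_re else NULL,
    latent = if (keep_latent) latent else NULL
  )
  list(table = ot_from_matrix(values, layer = layer, transform = "raw"),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
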