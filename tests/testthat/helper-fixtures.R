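# small programmatic fixtures shared across test files

toy_table <- function(layer = "MGN", n = 6, p = 4, seed = 1, transform = "raw") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * p, 20), n, p,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("%s_f%02d", layer, seq_len(p))))
    df <- tibble::tibble(sample_id = rownames(m), tibble::as_tibble(m))
    omic_table(df, layer = layer, transform = "raw")
  })
}

toy_meta <- function(sample_ids, participant_ids = sample_ids,
                     diagnosis = NULL, site = "site1", week = 0) {
  n <- length(sample_ids)
  if (is.null(diagnosis)) diagnosis <- rep(c("CD", "nonIBD"), length.out = n)
  tibble::tibble(
    sample_id = sample_ids, participant_id = participant_ids,
    diagnosis = diagnosis, age = 30, sex = rep(c("female", "male"), length.out = n),
    race = "White", antibiotic_use = FALSE, site = site, week = week
  ) |> as_cohort_metadata()
}

# per-sample model data for solver tests: logistic outcome, optional grouping
solver_data <- function(n = 200, p = 5, beta = NULL, seed = 1,
                        grouped = FALSE, n_groups = 20, re_sd = 0.7) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    if (is.null(beta)) beta <- c(1.5, -1.5, rep(0, p - 2))
    eta <- drop(X %*% beta)
    if (grouped) {
      g <- sample(n_groups, n, replace = TRUE)
      eta <- eta + rnorm(n_groups, 0, re_sd)[g]
      part <- sprintf("p%02d", g)
    } else {
      part <- "p1"
    }
    y <- rbinom(n, 1, plogis(eta))
    tibble::tibble(
      ibd = y, tibble::as_tibble(X), age = rnorm(n, 30, 8),
      sex = sample(c("female", "male"), n, TRUE), race = "White",
      antibiotic_use = FALSE, site = "s1", participant_id = part
    )
  })
}

# one-layer longitudinal cohort with planted effects, for recovery tests
recovery_design <- function(seed, n_participants = 130, n_cases = 80,
                            n_features = 50, n_causal = 5, effect_size = 2,
                            participant_re_sd = 0.5) {
  simulation_design(
    n_participants = n_participants, n_cases = n_cases, n_sites = 5,
    weeks = seq(0L, 12L, by = 4L),
    layers = list(MGN = layer_design(
      n_features, n_causal, effect_size = effect_size, base_log_mean = 0,
      base_log_sd = 1.5, library_size = 1e4, zero_inflation = 0,
      missing_layer_prob = 0, noise_sd = 0.5)),
    participant_re_sd = participant_re_sd, site_re_sd = 0.25, seed = seed
  )
}

# fit the single-layer scoring pipeline on a simulated cohort; returns
# selected features, the planted causal set, and validation AUC
fit_single_layer <- function(sim, n_validation = 30, n_lambda = 10) {
  meta <- sim$metadata
  tab <- clr_transform(sim$tables$MGN)
  split <- make_split(meta, sim$tables["MGN"], n_validation)
  meta <- dplyr::left_join(meta, split[c("participant_id", "set")],
                           by = "participant_id")
  meta$ibd <- ibd_label(meta$diagnosis)
  train_tab <- omic_table(tab[tab$sample_id %in%
                                meta$sample_id[meta$set == "train"], ], "MGN", "clr")
  valid_tab <- omic_table(tab[tab$sample_id %in%
                                meta$sample_id[meta$set == "validation"], ], "MGN", "clr")
  train_data <- dplyr::inner_join(tibble::as_tibble(train_tab), meta, by = "sample_id")
  spec <- mixed_model_spec(train_data, "ibd", feature_ids(tab))
  grid <- lambda_grid(spec, n_points = n_lambda, min_ratio = 0.05)
  path <- lasso_path(spec, grid, tol = 1e-7, max_iter = 100,
                     max_selected = 30)
  lam <- suppressWarnings(select_lambda_elbow(path))
  selected <- path$selected[[attr(lam, "index")]]
  out <- list(selected = selected, causal = sim$truth$layers$MGN$causal,
              auc = NA_real_, or = NULL)
  if (!length(selected)) return(out)
  refit <- suppressWarnings(refit_glmm(train_data, "ibd", selected))
  sm <- score_model(refit, train_tab)
  val_scores <- compute_scores(valid_tab, sm)
  pdata <- average_by_participant(val_scores, meta) |>
    dplyr::inner_join(dplyr::distinct(meta, participant_id, diagnosis),
                      by = "participant_id") |>
    dplyr::mutate(ibd = ibd_label(diagnosis))
  out$auc <- roc_auc(pdata$score, pdata$ibd)$auc
  out$or <- or_per_sd(pdata$ibd, pdata$score)
  out
}
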