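#' Analysis configuration
#'
#' Tunables for [run_polyomic()]. `filter_scope` and `standardize_scope`
#' control whether feature filters and score standardization constants are
#' fit on training samples only (the leakage-free default) or on all/pooled
#' samples.
#'
#' @param n_validation validation-set size in participants.
#' @param lambda_points,lambda_min_ratio penalty-grid shape, see
#'   [lambda_grid()].
#' @param max_selected path truncation bound, see [lasso_path()].
#' @param filter_scope `"train"` or `"all"`.
#' @param standardize_scope `"train"` or `"pooled"`.
#' @param pseudocount_clr,pseudocount_log10 pseudocounts for the two
#'   normalizations.
#' @param seed master seed; stage-level streams (collinearity filter,
#'   simulation) are derived from it.
#' @return an `analysis_config` list.
#' @export
polyomic_config <- function(n_validation = 30, lambda_points = 15,
                            lambda_min_ratio = 0.05, max_selected = 60,
                            filter_scope = c("train", "all"),
                            standardize_scope = c("train", "pooled"),
                            pseudocount_clr = 0.5, pseudocount_log10 = 1,
                            seed = 1) {
  structure(
    list(n_validation = n_validation, lambda_points = lambda_points,
         lambda_min_ratio = lambda_min_ratio, max_selected = max_selected,
         filter_scope = match.arg(filter_scope),
         standardize_scope = match.arg(standardize_scope),
         pseudocount_clr = pseudocount_clr,
         pseudocount_log10 = pseudocount_log10, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

stage_seed <- function(master, stage) {
  offsets <- c(collinearity = 11L, simulation = 12L, solver = 13L)
  as.integer((as.numeric(master) + 6007 * offsets[[stage]]) %% 2147483629)
}

#' Run the full poly-omic risk-score analysis
#'
#' End-to-end orchestration: (optionally) simulate a cohort, align layers
#' to metadata, split participants into training and validation, then per
#' layer: preprocess (filters fit on training samples), fit the penalty
#' path on training samples, pick the elbow lambda, refit the unpenalized
#' mixed model on the selected features, score validation samples, average
#' per participant and evaluate (covariate-adjusted and score-only), plus
#' a metadata-only baseline per layer. Finally the combined multi-omic
#' model and its leave-one-omic-out variants are fitted on validation
#' participants averaged over samples with every layer present. A run
#' manifest captures configuration, seeds, stage bookkeeping and content
#' hashes.
#'
#' @param x either a named list of raw [omic_table()]s or a
#'   [simulation_design()] (then `metadata` is ignored and the cohort is
#'   simulated).
#' @param metadata cohort metadata tibble (when `x` is a table list).
#' @param config an [polyomic_config()].
#' @return a `polyomic_run` list: `metadata`, `split`, `layers` (per-layer
#'   results), `evaluations` (tibble of all evaluation reports),
#'   `combined`, `loo`, `truth` (when simulated), `manifest`.
#' @export
run_polyomic <- function(x, metadata = NULL, config = polyomic_config()) {
  truth <- NULL
  if (inherits(x, "simulation_design")) {
    sim <- simulate_cohort(x)
    tables <- sim$tables
    metadata <- sim$metadata
    truth <- sim$truth
  } else {
    tables <- x
    if (is.null(metadata)) {
      abort("metadata required when supplying tables", class = "polyomics_error_spec")
    }
  }
  tables <- lapply(tables, align_samples, meta = metadata, quiet = TRUE)

  split <- make_split(metadata, tables, config$n_validation)
  meta <- dplyr::left_join(metadata, split[c("participant_id", "set")],
                           by = "participant_id")
  meta$ibd <- ibd_label(meta$diagnosis)
  train_participants <- split$participant_id[split$set == "train"]
  train_samples <- meta$sample_id[meta$set == "train"]

  part_info <- dplyr::distinct(meta, .data$participant_id, .data$diagnosis,
                               .data$age, .data$sex, .data$set)
  part_info$ibd <- ibd_label(part_info$diagnosis)

  layers <- list()
  evals <- list()
  for (layer in names(tables)) {
    layers[[layer]] <- run_layer(tables[[layer]], meta, config)
    lr <- layers[[layer]]
    if (!is.null(lr$evaluation)) {
      evals[[length(evals) + 1]] <- dplyr::bind_rows(
        dplyr::mutate(lr$evaluation$adjusted, layer = layer, mode = "adjusted"),
        dplyr::mutate(lr$evaluation$score_only, layer = layer, mode = "score_only"),
        if (!is.null(lr$evaluation$baseline)) {
          dplyr::mutate(lr$evaluation$baseline, layer = layer, mode = "baseline")
        }
      )
    }
  }

  combined <- NULL
  loo <- NULL
  scored_layers <- names(layers)[vapply(layers, function(l) !is.null(l$score_model),
                                        logical(1))]
  if (length(tables) < 2) {
    warn("single layer: combined stage skipped", class = "polyomics_warn_combined")
  } else if (length(scored_layers) < length(tables)) {
    warn("not all layers produced score models: combined stage skipped",
         class = "polyomics_warn_combined")
  } else {
    cw <- combined_scores(tables, layers, meta)
    if (!is.null(cw)) {
      cdata <- dplyr::inner_join(cw, part_info, by = "participant_id")
      combined <- tryCatch(
        fit_combined(cdata, layers = names(tables)),
        error = function(e) { warn(conditionMessage(e)); NULL }
      )
      if (!is.null(combined)) {
        loo <- leave_one_omic_out(cdata, layers = names(tables))
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("polyomics")),
    seed = config$seed,
    config = unclass(config),
    n_samples = nrow(metadata),
    n_participants = dplyr::n_distinct(metadata$participant_id),
    validation_fraction_pct = fraction_pct(config$n_validation,
                                           dplyr::n_distinct(metadata$participant_id),
                                           digits = 0),
    split = split,
    layer_summary = layer_summary_tbl(layers),
    hashes = c(
      lapply(tables, function(t) rlang::hash(ot_matrix(t))),
      list(metadata = rlang::hash(as.data.frame(metadata)),
           split = rlang::hash(as.data.frame(split)))
    )
  )

  structure(
    list(metadata = meta, split = split, layers = layers,
         evaluations = if (length(evals)) dplyr::bind_rows(evals) else NULL,
         combined = combined, loo = loo, truth = truth, config = config,
         manifest = manifest),
    class = "polyomic_run"
  )
}

run_layer <- function(table, meta, config) {
  layer <- ot_layer(table)
  cfg <- default_layer_config(layer, seed = stage_seed(config$seed, "collinearity"))
  if (cfg$transform == "clr") cfg$pseudocount <- config$pseudocount_clr
  if (cfg$transform == "log10") cfg$pseudocount <- config$pseudocount_log10
  fit_samples <- if (config$filter_scope == "train") {
    intersect(sample_ids(table), meta$sample_id[meta$set == "train"])
  } else NULL
  pp <- run_preprocess(table, cfg, fit_samples = fit_samples)
  feats <- feature_ids(pp$table)
  out <- list(report = pp$report, table = pp$table, n_features_raw =
                length(feature_ids(table)), n_features_qc = length(feats))
  if (!length(feats)) {
    warn(sprintf("%s: no features survive filtering", layer))
    return(out)
  }

  train_tab <- pp$table[pp$table$sample_id %in%
                          meta$sample_id[meta$set == "train"], , drop = FALSE]
  valid_tab <- pp$table[pp$table$sample_id %in%
                          meta$sample_id[meta$set == "validation"], , drop = FALSE]
  train_tab <- omic_table(train_tab, layer, ot_transform(pp$table))
  valid_tab <- omic_table(valid_tab, layer, ot_transform(pp$table))
  train_data <- dplyr::inner_join(tibble::as_tibble(train_tab), meta,
                                  by = "sample_id")

  spec <- mixed_model_spec(train_data, response = "ibd", features = feats)
  grid <- lambda_grid(spec, n_points = config$lambda_points,
                      min_ratio = config$lambda_min_ratio)
  path <- lasso_path(spec, grid, tol = 1e-7, max_iter = 100,
                     max_selected = config$max_selected)
  lam <- withCallingHandlers(
    tryCatch(select_lambda_elbow(path), error = function(e) {
      # path too short for the elbow rule (early truncation): use the
      # half-max-count fallback over the points that were fitted
      ok <- which(!is.na(path$n_selected))
      idx <- ok[which.min(abs(path$n_selected[ok] -
                                max(path$n_selected[ok]) / 2))]
      structure(path$lambda[idx], index = idx, fallback = TRUE)
    }),
    polyomics_warn_no_elbow = function(w) invokeRestart("muffleWarning")
  )
  selected <- path$selected[[attr(lam, "index")]]
  out$path <- path
  out$lambda <- as.numeric(lam)
  out$selected <- selected
  out$pct_selected <- selection_fraction(length(selected), length(feats))
  inform(sprintf("%s: selected %d of %d features (%.2f%%) at lambda %.4g",
                 layer, length(selected), length(feats), out$pct_selected,
                 out$lambda))
  if (!length(selected)) return(out)

  refit <- refit_glmm(train_data, response = "ibd", features = selected)
  ref_tab <- if (config$standardize_scope == "train") train_tab else pp$table
  smodel <- tryCatch(score_model(refit, ref_tab),
                     error = function(e) { warn(conditionMessage(e)); NULL })
  out$refit <- refit
  out$score_model <- smodel
  if (is.null(smodel)) return(out)
  out$cooccurrence <- cooccurrence(train_tab, selected)

  val_scores <- compute_scores(valid_tab, smodel)
  part_scores <- average_by_participant(val_scores, meta)
  pdata <- part_scores |>
    dplyr::inner_join(
      dplyr::distinct(meta, .data$participant_id, .data$diagnosis, .data$age,
                      .data$sex),
      by = "participant_id") |>
    dplyr::mutate(ibd = ibd_label(.data$diagnosis))
  out$sample_scores <- val_scores
  out$participant_scores <- pdata

  evaluation <- list(
    adjusted = evaluate_layer(pdata, score = "score", label = "ibd",
                              covariates = c("age", "sex"),
                              model_label = paste0(layer, "_score")),
    score_only = evaluate_layer(pdata, score = "score", label = "ibd",
                                covariates = character(0),
                                model_label = paste0(layer, "_score_only"))
  )

  # metadata-only baseline trained on this layer's training samples
  base <- tryCatch(
    fit_baseline(meta[meta$set == "train" & meta$sample_id %in%
                        sample_ids(train_tab), , drop = FALSE]),
    error = function(e) NULL
  )
  if (!is.null(base)) {
    vmeta <- meta[meta$set == "validation" & meta$sample_id %in%
                    sample_ids(valid_tab), , drop = FALSE]
    pred_train <- predict_refit(base, meta[meta$set == "train" &
                                             meta$sample_id %in%
                                             sample_ids(train_tab), ,
                                           drop = FALSE])
    pred <- predict_refit(base, vmeta)
    z <- if (sd(pred_train) > 0) {
      (pred - mean(pred_train)) / sd(pred_train)
    } else pred
    bdata <- tibble::tibble(sample_id = vmeta$sample_id, layer = layer,
                            raw = pred, standardized = z) |>
      average_by_participant(meta) |>
      dplyr::inner_join(
        dplyr::distinct(meta, .data$participant_id, .data$diagnosis),
        by = "participant_id") |>
      dplyr::mutate(ibd = ibd_label(.data$diagnosis))
    evaluation$baseline <- tryCatch(
      evaluate_layer(bdata, score = "score", label = "ibd",
                     covariates = character(0),
                     model_label = paste0(layer, "_baseline")),
      error = function(e) NULL
    )
    out$baseline <- base
  }
  out$evaluation <- evaluation
  out
}

# participant-level wide score table over validation samples with every
# layer present
combined_scores <- function(tables, layers, meta) {
  common <- Reduce(intersect, lapply(tables, sample_ids))
  common <- intersect(common, meta$sample_id[meta$set == "validation"])
  if (!length(common)) {
    warn("no validation samples with all layers present",
         class = "polyomics_warn_combined")
    return(NULL)
  }
  per_layer <- purrr::imap(layers, function(lr, layer) {
    tab <- lr$table[lr$table$sample_id %in% common, , drop = FALSE]
    tab <- omic_table(tab, layer, ot_transform(lr$table))
    sc <- compute_scores(tab, lr$score_model)
    average_by_participant(sc, meta)
  })
  dplyr::bind_rows(per_layer) |>
    dplyr::select("participant_id", "layer", "score") |>
    tidyr::pivot_wider(names_from = "layer", values_from = "score")
}

layer_summary_tbl <- function(layers) {
  purrr::imap_dfr(layers, function(lr, layer) {
    tibble::tibble(
      layer = layer,
      features_raw = lr$n_features_raw %||% NA_integer_,
      features_qc = lr$n_features_qc %||% NA_integer_,
      n_selected = length(lr$selected %||% character(0)),
      pct_selected = lr$pct_selected %||% NA_real_,
      lambda = lr$lambda %||% NA_real_
    )
  })
}

#' @export
print.polyomic_run <- function(x, ...) {
  cat("<polyomic_run>\n")
  print(x$manifest$layer_summary)
  if (!is.null(x$combined)) print(x$combined)
  invisible(x)
}
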