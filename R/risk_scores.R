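#' Participant-level train/validation split
#'
#' Partitions participants (never individual samples) into training and
#' validation sets. Because the combined multi-omic model needs samples
#' with all layers present, the `n_validation` participants with the most
#' complete-all-layer samples — ties broken by the fewest samples missing
#' at least one layer, then by participant ID — form the validation set.
#' All of a participant's samples share its assignment, so no validation
#' sample can leak into training.
#'
#' @param meta cohort metadata tibble.
#' @param inventories named list (one element per layer) of the sample IDs
#'   present in that layer; [omic_table()]s are also accepted.
#' @param n_validation number of validation participants.
#' @return a `split_assignment` tibble: `participant_id`, `n_complete`,
#'   `n_incomplete`, `set` (train/validation).
#' @export
make_split <- function(meta, inventories, n_validation) {
  if (n_validation <= 0) {
    abort("n_validation must be positive", class = "polyomics_error_value")
  }
  ids <- lapply(inventories, function(x) {
    if (inherits(x, "omic_table")) sample_ids(x) else as.character(x)
  })
  n_part <- dplyr::n_distinct(meta$participant_id)
  if (n_validation >= n_part) {
    abort("n_validation must be smaller than the number of participants",
          class = "polyomics_error_value")
  }
  n_layers_present <- rowSums(vapply(ids, function(v) meta$sample_id %in% v,
                                     logical(nrow(meta))))
  counts <- meta |>
    dplyr::mutate(complete = n_layers_present == length(ids)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_complete = sum(.data$complete),
                     n_incomplete = sum(!.data$complete), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_complete), .data$n_incomplete,
                   .data$participant_id)
  counts$set <- c(rep("validation", n_validation),
                  rep("train", nrow(counts) - n_validation))
  out <- dplyr::arrange(counts, .data$participant_id)
  class(out) <- c("split_assignment", class(out))
  out
}

#' Standardize raw risk scores against a reference set
#'
#' `z = (x - mean(ref)) / sd(ref)` with the sample (n-1) SD. The reference
#' set is the training scores in the pipeline, so validation scores are
#' expressed on the training scale (no leakage).
#'
#' @param raw numeric raw scores to standardize.
#' @param reference numeric reference scores the constants are computed on;
#'   defaults to `raw`.
#' @return list with `mean`, `sd` and `z` (standardized `raw`).
#' @export
standardize_scores <- function(raw, reference = raw) {
  m <- mean(reference)
  s <- sd(reference)
  if (!is.finite(s) || s <= 0) {
    abort("reference scores have zero variance; cannot standardize",
          class = "polyomics_error_standardization")
  }
  list(mean = m, sd = s, z = (raw - m) / s)
}

#' Build a per-layer score model from a mixed-model refit
#'
#' Bundles the refit feature weights (demographic covariates are excluded
#' by construction) with the standardization constants computed on the
#' reference (training) samples of the transformed table, producing the
#' object that turns any sample's feature values into a standardized risk
#' score.
#'
#' @param refit a `polyomic_refit` from [refit_glmm()].
#' @param reference transformed [omic_table()] of the reference (training)
#'   samples used for standardization constants.
#' @return a `score_model`: layer, feature IDs, weights, constants.
#' @export
score_model <- function(refit, reference) {
  features <- names(refit$feature_coef)
  missing_feats <- setdiff(features, feature_ids(reference))
  if (length(missing_feats)) {
    abort(paste0("reference table lacks features: ",
                 paste(missing_feats, collapse = ", ")),
          class = "polyomics_error_scoring")
  }
  raw <- drop(ot_matrix(reference)[, features, drop = FALSE] %*% refit$feature_coef)
  std <- standardize_scores(raw)
  structure(
    list(layer = ot_layer(reference), transform = ot_transform(reference),
         features = features, weights = refit$feature_coef,
         center = std$mean, scale = std$sd, engine = refit$engine),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model: %s (%s), %d features, center %.3f, scale %.3f>\n",
              x$layer, x$transform, length(x$features), x$center, x$scale))
  invisible(x)
}

#' Compute per-sample risk scores
#'
#' Evaluates the weighted sum `score_i = beta_1 * feature_1i + ... +
#' beta_n * feature_ni` for each sample of a transformed table and
#' standardizes it with the model's stored constants. Demographic
#' covariates never contribute to the score.
#'
#' @param x transformed [omic_table()] containing all model features, in
#'   the transform the model was trained on.
#' @param model a [score_model()].
#' @return tibble `sample_id`, `layer`, `raw`, `standardized`.
#' @export
compute_scores <- function(x, model) {
  if (ot_transform(x) != model$transform) {
    abort(sprintf("table transform '%s' does not match model transform '%s'",
                  ot_transform(x), model$transform),
          class = "polyomics_error_scoring")
  }
  missing_feats <- setdiff(model$features, feature_ids(x))
  if (length(missing_feats)) {
    abort(paste0("table lacks model features: ",
                 paste(missing_feats, collapse = ", ")),
          class = "polyomics_error_scoring")
  }
  raw <- drop(ot_matrix(x)[, model$features, drop = FALSE] %*% model$weights)
  tibble::tibble(sample_id = sample_ids(x), layer = model$layer,
                 raw = as.numeric(raw),
                 standardized = (as.numeric(raw) - model$center) / model$scale)
}

#' Average standardized scores per participant
#'
#' The arithmetic mean of a participant's standardized sample scores across
#' their longitudinal samples (averaging happens after standardization).
#'
#' @param scores tibble from [compute_scores()].
#' @param meta cohort metadata (maps samples to participants).
#' @return tibble `participant_id`, `layer`, `score`, `n_samples`.
#' @export
average_by_participant <- function(scores, meta) {
  scores |>
    dplyr::inner_join(meta[c("sample_id", "participant_id")], by = "sample_id") |>
    dplyr::group_by(.data$participant_id, .data$layer) |>
    dplyr::summarise(score = mean(.data$standardized),
                     n_samples = dplyr::n(), .groups = "drop")
}

#' Metadata-only baseline model
#'
#' Fits the mixed logistic model `diagnosis ~ age + sex + race +
#' antibiotic_use + (1|site) + (1|participant)` on training samples only —
#' no omic features — establishing how much of the diagnosis is predictable
#' from demographics alone.
#'
#' @param train_meta training-set metadata tibble.
#' @return a `polyomic_refit` with zero feature weights.
#' @export
fit_baseline <- function(train_meta) {
  data <- dplyr::mutate(train_meta, ibd = ibd_label(.data$diagnosis))
  if (length(unique(data$ibd)) < 2) {
    abort("training metadata needs both classes", class = "polyomics_error_spec")
  }
  refit_glmm(data, response = "ibd", features = character(0))
}

#' Population-level predictions from a mixed-model refit
#'
#' Linear-predictor (log-odds) predictions for new samples using fixed
#' effects only (`re.form = NA`): validation participants are new grouping
#' levels, so their random intercepts are taken as zero. Factor covariate
#' levels unseen in training are mapped to the training reference level,
#' with a warning.
#'
#' @param object a `polyomic_refit`.
#' @param newdata per-sample tibble with the model's covariate columns.
#' @return numeric vector of link-scale predictions.
#' @export
predict_refit <- function(object, newdata) {
  newdata <- dplyr::mutate(tibble::as_tibble(newdata),
                           dplyr::across(dplyr::where(is.character), factor))
  frame <- if (inherits(object$fit, "merMod")) object$fit@frame else object$fit$model
  for (col in intersect(names(frame), names(newdata))) {
    if (is.factor(frame[[col]])) {
      lv <- levels(frame[[col]])
      v <- as.character(newdata[[col]])
      if (any(!v %in% lv)) {
        warn(sprintf("unseen levels in '%s' mapped to reference level", col),
             class = "polyomics_warn_new_levels")
        v[!v %in% lv] <- lv[1]
      }
      newdata[[col]] <- factor(v, levels = lv)
    }
  }
  if (inherits(object$fit, "merMod")) {
    as.numeric(predict(object$fit, newdata = newdata, re.form = NA,
                       allow.new.levels = TRUE, type = "link"))
  } else {
    as.numeric(predict(object$fit, newdata = newdata, type = "link"))
  }
}
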