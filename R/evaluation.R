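#' AUC with DeLong confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' random case scores above a random control (ties count one half), with a
#' 95% CI from DeLong's asymptotic variance.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return one-row tibble `auc`, `auc_lo`, `auc_hi`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("both classes required to compute AUC",
          class = "polyomics_error_evaluation")
  }
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  tibble::tibble(auc = as.numeric(pROC::auc(r)),
                 auc_lo = max(0, ci[1]), auc_hi = min(1, ci[3]))
}

#' Odds ratio per standard deviation of a risk score
#'
#' Plain logistic regression of the label on the (standardized) score,
#' optionally adjusted for covariates; the OR for a one-SD score increase
#' is `exp(beta_score)` with a Wald 95% CI `exp(beta +/- 1.96 SE)` and Wald
#' p-value. Complete separation (diverging coefficient) is flagged and the
#' CI reported as unbounded.
#'
#' @param labels 0/1 vector.
#' @param score numeric standardized score.
#' @param covariates optional data frame of adjustment covariates (e.g.
#'   age, sex).
#' @return one-row tibble `or`, `or_lo`, `or_hi`, `p`, `separation`.
#' @export
or_per_sd <- function(labels, score, covariates = NULL) {
  df <- data.frame(.y = as.integer(labels), .score = as.numeric(score))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  if (!".score" %in% rownames(sm)) {
    # constant score column: no effect estimable, OR is 1 by definition
    return(tibble::tibble(or = 1, or_lo = 0, or_hi = Inf, p = NA_real_,
                          separation = FALSE))
  }
  b <- sm[".score", "Estimate"]
  se <- sm[".score", "Std. Error"]
  separation <- !fit$converged || abs(b) > 15 || se > 100
  if (separation) {
    warn("possible separation in OR model; CI unbounded",
         class = "polyomics_warn_separation")
    return(tibble::tibble(or = exp(b), or_lo = 0, or_hi = Inf,
                          p = NA_real_, separation = TRUE))
  }
  tibble::tibble(or = exp(b), or_lo = exp(b - 1.96 * se),
                 or_hi = exp(b + 1.96 * se),
                 p = 2 * pnorm(-abs(b / se)), separation = FALSE)
}

#' Nagelkerke's pseudo R-squared
#'
#' Rescales the Cox-Snell R-squared `1 - exp(2 (L0 - L1) / n)` by its
#' maximum attainable value `1 - exp(2 L0 / n)` so a perfectly predicting
#' model reaches 1 and a model no better than the null scores 0.
#'
#' @param l1 maximized log-likelihood of the model.
#' @param l0 log-likelihood of the nested null model (`l0 <= l1`).
#' @param n number of observations.
#' @return the pseudo R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(l1, l0, n) {
  if (n <= 0) abort("n must be positive", class = "polyomics_error_value")
  r2_cs <- 1 - exp(2 * (l0 - l1) / n)
  denom <- 1 - exp(2 * l0 / n)
  if (denom <= 0) return(0)
  min(max(r2_cs / denom, 0), 1)
}

#' Evaluate one layer's participant-level risk scores
#'
#' Bundles AUC (DeLong CI), OR per SD (optionally adjusted for age and
#' sex), and Nagelkerke R-squared of the score model against the
#' intercept-only null, for one set of participant-averaged scores and
#' labels.
#'
#' @param data per-participant tibble with the score, label and covariate
#'   columns.
#' @param score name of the score column.
#' @param label name of the 0/1 label column.
#' @param covariates covariate column names to adjust for (`NULL` or
#'   `character(0)` for the score-only variant).
#' @param model_label label recorded in the report.
#' @return one-row `evaluation_report` tibble.
#' @export
evaluate_layer <- function(data, score = "score", label = "ibd",
                           covariates = c("age", "sex"), model_label = score) {
  data <- tibble::as_tibble(data)
  y <- as.integer(data[[label]])
  s <- as.numeric(data[[score]])
  a <- roc_auc(s, y)
  covs <- if (length(covariates)) data[covariates] else NULL
  orr <- or_per_sd(y, s, covs)
  df <- data.frame(.y = y, .score = s)
  if (!is.null(covs)) df <- cbind(df, as.data.frame(covs))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  null <- glm(.y ~ 1, data = df, family = binomial())
  r2 <- nagelkerke_r2(as.numeric(logLik(fit)), as.numeric(logLik(null)),
                      length(y))
  out <- tibble::tibble(
    model = model_label, auc = a$auc, auc_lo = a$auc_lo, auc_hi = a$auc_hi,
    or = orr$or, or_lo = orr$or_lo, or_hi = orr$or_hi, or_p = orr$p,
    r2 = r2, n_cases = sum(y == 1), n_controls = sum(y == 0)
  )
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Combined multi-omic logistic model
#'
#' Fits `diagnosis ~ MGN + MTS + VRM + MBL + age + sex` (ordinary logistic
#' regression; validation data collapse to one averaged row per
#' participant) on participants with every layer scored, plus the age+sex
#' reduction, reporting Nagelkerke R-squared of both against the
#' intercept-only null, the combined-prediction AUC, per-layer ORs with
#' Wald CIs, and the between-score Pearson correlation matrix. Perfectly
#' collinear scores trigger a warning (their coefficients are
#' unidentifiable).
#'
#' @param data per-participant tibble with one score column per layer plus
#'   `age`, `sex` and the label column.
#' @param layers score column names entering the model; all must be
#'   present in `data`.
#' @param label 0/1 label column name.
#' @param covariates demographic covariates retained in the combined model.
#' @return a `combined_result`: coefficient tibble with per-layer ORs,
#'   `r2_full`, `r2_covariates`, `delta_r2`, `auc`, `cor_matrix`,
#'   `loglik`, `n`.
#' @export
fit_combined <- function(data, layers = OMIC_LAYERS, label = "ibd",
                         covariates = c("age", "sex")) {
  data <- tibble::as_tibble(data)
  missing_layers <- setdiff(layers, names(data))
  if (length(missing_layers)) {
    abort(paste0("combined model needs score columns: ",
                 paste(missing_layers, collapse = ", ")),
          class = "polyomics_error_combined")
  }
  keep <- stats::complete.cases(data[c(layers, covariates, label)])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < length(layers) + length(covariates) + 2) {
    abort("too few complete-case participants for the combined model",
          class = "polyomics_error_combined")
  }
  y <- as.integer(data[[label]])
  sc <- as.matrix(data[layers])
  cm <- suppressWarnings(cor(sc))
  if (any(abs(cm[upper.tri(cm)]) > 0.999)) {
    warn("perfectly collinear scores: coefficients unidentifiable",
         class = "polyomics_warn_collinear")
  }

  form_full <- stats::as.formula(
    paste(label, "~", paste(c(layers, covariates), collapse = " + ")))
  form_cov <- stats::as.formula(
    paste(label, "~", paste(c(covariates, "1"), collapse = " + ")))
  full <- suppressWarnings(glm(form_full, data = data, family = binomial()))
  covm <- suppressWarnings(glm(form_cov, data = data, family = binomial()))
  nullm <- glm(stats::as.formula(paste(label, "~ 1")), data = data,
               family = binomial())
  l_full <- as.numeric(logLik(full))
  l_cov <- as.numeric(logLik(covm))
  l_null <- as.numeric(logLik(nullm))
  n <- nrow(data)

  sm <- summary(full)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm), estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    or = exp(sm[, "Estimate"]),
    or_lo = exp(sm[, "Estimate"] - 1.96 * sm[, "Std. Error"]),
    or_hi = exp(sm[, "Estimate"] + 1.96 * sm[, "Std. Error"]),
    p = sm[, "Pr(>|z|)"]
  )
  auc <- roc_auc(predict(full, type = "link"), y)
  structure(
    list(model = full, coefficients = coefs, layers = layers,
         r2_full = nagelkerke_r2(l_full, l_null, n),
         r2_covariates = nagelkerke_r2(l_cov, l_null, n),
         delta_r2 = nagelkerke_r2(l_full, l_null, n) -
           nagelkerke_r2(l_cov, l_null, n),
         auc = auc$auc, auc_lo = auc$auc_lo, auc_hi = auc$auc_hi,
         cor_matrix = cm, loglik = l_full, loglik_null = l_null, n = n),
    class = "combined_result"
  )
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf("<combined_result: %s; n = %d, R2 = %.3f (covariates %.3f), AUC = %.3f>\n",
              paste(x$layers, collapse = "+"), x$n, x$r2_full,
              x$r2_covariates, x$auc))
  invisible(x)
}

#' Leave-one-omic-out analysis of the combined model
#'
#' Refits the combined model once per layer with that layer's score
#' omitted, quantifying each layer's contribution as the drop in Nagelkerke
#' R-squared (and log-likelihood, which can never increase for the nested
#' reduced model).
#'
#' @inheritParams fit_combined
#' @return tibble with one row per omitted layer (`omitted`, `r2`, `auc`,
#'   `loglik`, `delta_r2` vs the full model); the full and reduced
#'   `combined_result`s are attached as attributes `full` and `variants`.
#' @export
leave_one_omic_out <- function(data, layers = OMIC_LAYERS, label = "ibd",
                               covariates = c("age", "sex")) {
  full <- fit_combined(data, layers = layers, label = label,
                       covariates = covariates)
  variants <- lapply(layers, function(l) {
    fit_combined(data, layers = setdiff(layers, l), label = label,
                 covariates = covariates)
  })
  names(variants) <- layers
  out <- purrr::map2_dfr(variants, layers, function(v, l) {
    tibble::tibble(omitted = l, r2 = v$r2_full, auc = v$auc,
                   loglik = v$loglik, delta_r2 = full$r2_full - v$r2_full)
  })
  attr(out, "full") <- full
  attr(out, "variants") <- variants
  out
}

#' Co-occurrence (Pearson correlation) of selected features
#'
#' Pairwise Pearson correlations of transformed abundances for a feature
#' subset; zero-variance features yield `NA` rows/columns with a warning.
#'
#' @param x transformed [omic_table()] with at least 2 samples.
#' @param features feature subset (default: all features).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
cooccurrence <- function(x, features = feature_ids(x)) {
  if (nrow(x) < 2) {
    abort("cooccurrence needs >= 2 samples", class = "polyomics_error_state")
  }
  missing_feats <- setdiff(features, feature_ids(x))
  if (length(missing_feats)) {
    abort(paste0("features not in table: ", paste(missing_feats, collapse = ", ")),
          class = "polyomics_error_value")
  }
  m <- ot_matrix(x)[, features, drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn("zero-variance features: correlations undefined (NA)",
         class = "polyomics_warn_zero_variance")
  }
  cm <- suppressWarnings(cor(m))
  diag(cm) <- 1
  cm
}
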