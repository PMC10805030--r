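#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_vline
#'   geom_boxplot geom_jitter geom_errorbarh geom_hline labs scale_x_log10
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a penalized mixed-model fit
#'
#' One row per penalized feature with a nonzero coefficient (set
#' `all = TRUE` for the full block), on the original feature scale.
#'
#' @param x a `penalized_fit`.
#' @param all include zero coefficients.
#' @param ... unused.
#' @return tibble `term`, `estimate`.
#' @export
tidy.penalized_fit <- function(x, all = FALSE, ...) {
  out <- tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
  if (!all) out <- out[out$estimate != 0, , drop = FALSE]
  out
}

#' @rdname tidy.penalized_fit
#' @export
glance.penalized_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = length(x$selected),
                 objective = x$objective, iterations = x$iterations,
                 converged = x$converged, n_obs = x$n_obs)
}

#' Tidy an unpenalized mixed-model refit
#'
#' @param x a `polyomic_refit`.
#' @param ... unused.
#' @return tibble `term`, `estimate`, `is_feature`.
#' @export
tidy.polyomic_refit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 is_feature = names(x$coefficients) %in% names(x$feature_coef))
}

#' @rdname tidy.polyomic_refit
#' @export
glance.polyomic_refit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_obs = x$n_obs, engine = x$engine,
                 n_features = length(x$feature_coef))
}

#' Tidy a combined multi-omic model
#'
#' @param x a `combined_result`.
#' @param ... unused.
#' @return the coefficient tibble with ORs and Wald CIs.
#' @export
tidy.combined_result <- function(x, ...) x$coefficients

#' @rdname tidy.combined_result
#' @export
glance.combined_result <- function(x, ...) {
  tibble::tibble(r2_full = x$r2_full, r2_covariates = x$r2_covariates,
                 delta_r2 = x$delta_r2, auc = x$auc, logLik = x$loglik,
                 n = x$n)
}

#' Tidy a full pipeline run
#'
#' One row per layer and evaluation mode, combining the bookkeeping
#' (features pre/post filtering, selected counts and percentages) with the
#' evaluation metrics.
#'
#' @param x a `polyomic_run`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.polyomic_run <- function(x, ...) {
  summary_tbl <- x$manifest$layer_summary
  if (is.null(x$evaluations)) return(summary_tbl)
  dplyr::left_join(x$evaluations, summary_tbl, by = "layer")
}

#' @rdname tidy.polyomic_run
#' @export
glance.polyomic_run <- function(x, ...) {
  tibble::tibble(
    n_participants = x$manifest$n_participants,
    n_samples = x$manifest$n_samples,
    n_validation = sum(x$split$set == "validation"),
    validation_pct = x$manifest$validation_fraction_pct,
    combined_r2 = if (!is.null(x$combined)) x$combined$r2_full else NA_real_,
    combined_auc = if (!is.null(x$combined)) x$combined$auc else NA_real_
  )
}

#' Plot the selected-feature count along the penalty path
#'
#' Selected-count versus lambda (log scale, decreasing penalty to the
#' right); the elbow chosen by [select_lambda_elbow()] is marked.
#'
#' @param object a `lambda_path`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lambda_path <- function(object, ...) {
  elbow <- tryCatch(suppressWarnings(select_lambda_elbow(object)),
                    error = function(e) NULL)
  p <- ggplot(object, aes(x = .data$lambda, y = .data$n_selected)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = expression(lambda), y = "features selected") +
    theme_minimal()
  if (!is.null(elbow)) {
    p <- p + geom_vline(xintercept = as.numeric(elbow), linetype = "dashed")
  }
  p
}

#' Participant risk scores by diagnosis
#'
#' Boxplots of participant-averaged standardized risk scores against the
#' binary diagnosis, per layer — the package's analogue of the headline
#' score-separation figure.
#'
#' @param run a `polyomic_run`.
#' @return a ggplot.
#' @export
plot_scores <- function(run) {
  dat <- purrr::imap_dfr(run$layers, function(lr, layer) {
    if (is.null(lr$participant_scores)) return(NULL)
    dplyr::mutate(lr$participant_scores, layer = layer)
  })
  if (!nrow(dat)) abort("no scored layers to plot", class = "polyomics_error_value")
  ggplot(dat, aes(x = factor(.data$ibd), y = .data$score)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~layer) +
    labs(x = "IBD diagnosis", y = "standardized risk score") +
    theme_minimal()
}

#' Forest plot of combined-model odds ratios
#'
#' @param object a `combined_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.combined_result <- function(object, ...) {
  dat <- object$coefficients[object$coefficients$term %in% object$layers, ]
  ggplot(dat, aes(x = .data$or, y = .data$term)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$or_lo, xmax = .data$or_hi), height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "OR per SD (95% CI)", y = NULL) +
    theme_minimal()
}
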