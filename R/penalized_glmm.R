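#' Specify a penalized mixed-effects logistic model
#'
#' Describes the model `diagnosis ~ features + covariates + (1|site) +
#' (1|participant)` fitted throughout the package: a binary response, a
#' penalized block of omic features (subject to the L1 penalty and hence
#' selection), unpenalized demographic covariates, and random intercepts
#' for grouping factors. All columns live in one tidy per-sample data
#' frame.
#'
#' @param data per-sample tibble holding response, features, covariates and
#'   grouping columns.
#' @param response name of the 0/1 response column (1 = case).
#' @param features character vector of penalized feature column names.
#' @param covariates unpenalized fixed-effect column names (never
#'   thresholded, never contributing to risk scores).
#' @param random grouping-factor column names for random intercepts;
#'   factors with fewer than 2 levels are dropped with a message.
#' @return a `mixed_model_spec`.
#' @export
mixed_model_spec <- function(data, response, features,
                             covariates = c("age", "sex", "race", "antibiotic_use"),
                             random = c("site", "participant_id")) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(response, features, covariates, random), names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not in data: ", paste(head(missing_cols, 5), collapse = ", ")),
          class = "polyomics_error_spec")
  }
  if (length(intersect(features, covariates))) {
    abort("features and covariates must be disjoint", class = "polyomics_error_spec")
  }
  y <- data[[response]]
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    abort("response must be binary 0/1 with both classes present",
          class = "polyomics_error_spec")
  }
  structure(
    list(data = data, response = response, features = features,
         covariates = covariates, random = random),
    class = "mixed_model_spec"
  )
}

# numeric design pieces for the solver
build_design <- function(spec, standardize = TRUE) {
  data <- spec$data
  y <- as.numeric(data[[spec$response]])
  Xp <- as.matrix(data[spec$features])
  storage.mode(Xp) <- "double"

  if (length(spec$covariates)) {
    cov_df <- data[spec$covariates]
    cov_df <- dplyr::mutate(cov_df, dplyr::across(dplyr::where(is.character), factor))
    # single-level factors carry no information and break contrasts
    keep <- vapply(cov_df, function(v) length(unique(v)) > 1, logical(1))
    cov_df <- cov_df[keep]
    Xc <- if (ncol(cov_df)) stats::model.matrix(~ ., cov_df) else
      matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xc <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  }

  ctr <- colMeans(Xp)
  scl <- apply(Xp, 2, sd)
  if (!standardize) {
    ctr <- rep(0, ncol(Xp))
    scl <- rep(1, ncol(Xp))
  }
  scl[!is.finite(scl) | scl == 0] <- 1
  Xps <- sweep(sweep(Xp, 2, ctr), 2, scl, "/")
  zero_var <- apply(Xps, 2, function(v) all(v == v[1]))
  Xps[, zero_var] <- 0

  groups <- list()
  for (g in spec$random) {
    f <- factor(data[[g]])
    if (nlevels(f) >= 2) groups[[g]] <- f
  }
  list(y = y, Xc = Xc, Xp = Xps, center = ctr, scale = scl, groups = groups)
}

#' Fit the L1-penalized mixed-effects logistic regression at one lambda
#'
#' Approximately maximizes the Laplace/PQL-approximated mixed-logistic
#' log-likelihood minus `lambda * sum(|beta|)` over the penalized feature
#' block, the unpenalized covariates, and the random-intercept variance
#' components, by alternating (a) coordinate-descent with soft-thresholding
#' on the working weighted least-squares problem (compiled kernel;
#' covariates and intercept never thresholded) and (b) closed-form
#' random-intercept and variance-component updates. Features are
#' standardized internally by default and coefficients reported on the
#' original scale. The penalized objective is tracked per outer iteration;
#' convergence is declared when its relative change falls below `tol`.
#'
#' @param spec a [mixed_model_spec()].
#' @param lambda nonnegative penalty weight (on the standardized scale when
#'   `standardize = TRUE`); `Inf` yields the covariate-only null fit.
#' @param init optional warm start (the `state` element of a previous fit).
#' @param standardize standardize the penalized block internally.
#' @param tol relative-objective convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @return a `penalized_fit`: feature coefficients (sparse, original
#'   scale), covariate coefficients, predicted random intercepts and
#'   variance per grouping factor, fitted probabilities, objective trace,
#'   and convergence diagnostics.
#' @export
fit_lasso_glmm <- function(spec, lambda, init = NULL, standardize = TRUE,
                           tol = 1e-8, max_iter = 200) {
  if (lambda < 0) abort("lambda must be >= 0", class = "polyomics_error_value")
  d <- build_design(spec, standardize = standardize)
  y <- d$y
  X <- cbind(d$Xc, d$Xp)
  qc <- ncol(d$Xc)
  p <- ncol(d$Xp)
  pen <- as.integer(c(rep(0L, qc), rep(1L, p)))
  n <- length(y)

  beta <- rep(0, qc + p)
  u <- lapply(d$groups, function(f) setNames(rep(0, nlevels(f)), levels(f)))
  sigma2 <- setNames(rep(0.05, length(d$groups)), names(d$groups))
  if (!is.null(init)) {
    if (length(init$beta) == length(beta)) beta <- init$beta
    if (length(init$u) == length(u)) u <- init$u
    if (length(init$sigma2) == length(sigma2)) sigma2 <- init$sigma2
  }

  re_part <- function() {
    re <- rep(0, n)
    for (g in names(d$groups)) re <- re + u[[g]][as.integer(d$groups[[g]])]
    re
  }
  lam_cd <- if (is.finite(lambda)) lambda else 1e300

  re <- re_part()
  eta <- drop(X %*% beta) + re
  obj_prev <- Inf
  obj_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w

    cd <- wls_lasso_cd(X, z - re, w, beta, pen, lam_cd, 1e-8, 500L)
    beta <- drop(cd$beta)
    fixed <- drop(X %*% beta)

    if (length(d$groups)) {
      for (g in names(d$groups)) {
        idx <- as.integer(d$groups[[g]])
        other <- re - u[[g]][idx]
        resid <- z - fixed - other
        sw <- tapply(w, idx, sum)
        swr <- tapply(w * resid, idx, sum)
        denom <- sw + 1 / sigma2[[g]]
        u_new <- swr / denom
        u[[g]][] <- as.numeric(u_new)
        # EM-style variance update with Laplace posterior variances
        sigma2[[g]] <- min(max((sum(u_new^2) + sum(1 / denom)) / length(u_new),
                               1e-10), 25)
        re <- other + u[[g]][idx]
      }
    }
    eta <- fixed + re

    cond_ll <- sum(y * eta - log1p(exp(eta)))
    pen_sum <- sum(abs(beta[pen == 1L]))
    pen_term <- if (pen_sum == 0) 0 else lambda * pen_sum
    re_term <- 0
    for (g in names(d$groups)) re_term <- re_term + sum(u[[g]]^2) / (2 * sigma2[[g]])
    obj <- -cond_ll + pen_term + re_term
    obj_trace <- c(obj_trace, obj)
    # converge on relative objective change, or on the joint parameter
    # vector stalling (PQL variance updates keep the objective wiggling at
    # a level the objective criterion alone may never reach)
    par <- c(beta, unlist(u, use.names = FALSE), sigma2)
    par_delta <- if (it > 1) max(abs(par - par_prev) / pmax(1, abs(par_prev)))
      else Inf
    par_prev <- par
    if ((is.finite(obj_prev) &&
         abs(obj - obj_prev) < tol * (abs(obj_prev) + 1e-10)) ||
        par_delta < 1e-6) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  beta_cov <- setNames(beta[seq_len(qc)], colnames(d$Xc))
  beta_std <- setNames(beta[qc + seq_len(p)], colnames(d$Xp))
  # coefficients at the soft-threshold boundary are zero up to round-off
  beta_std[abs(beta_std) < 1e-8] <- 0
  beta_feat <- beta_std / d$scale
  beta_cov[1] <- beta_cov[1] - sum(beta_std * d$center / d$scale)
  selected <- names(beta_feat)[beta_feat != 0]
  if (max(abs(beta)) > 30) {
    warn("very large coefficients: possible complete separation",
         class = "polyomics_warn_separation")
  }

  structure(
    list(
      lambda = lambda, beta = beta_feat, covariate_coef = beta_cov,
      selected = selected, ranef = u, sigma2 = sigma2,
      fitted = plogis(eta), eta = eta,
      converged = converged, iterations = it,
      objective = obj_trace[length(obj_trace)], obj_trace = obj_trace,
      standardize = standardize,
      state = list(beta = beta, u = u, sigma2 = sigma2),
      features = spec$features, n_obs = n
    ),
    class = "penalized_fit"
  )
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("<penalized_fit: lambda = %.4g, %d/%d features selected, %s>\n",
              x$lambda, length(x$selected), length(x$beta),
              if (x$converged) sprintf("converged in %d iters", x$iterations)
              else "NOT converged"))
  invisible(x)
}

#' Lambda grid for the penalty path
#'
#' Computes `lambda_max` as the largest absolute component of the score
#' equation for the penalized block at the null model (intercept,
#' covariates and random intercepts only; no features), so that the fit at
#' `lambda_max` selects no features, and returns `n_points` log-spaced
#' values from `lambda_max` down to `lambda_max * min_ratio`.
#'
#' @inheritParams fit_lasso_glmm
#' @param n_points number of grid points (>= 2).
#' @param min_ratio smallest grid value as a fraction of `lambda_max`.
#' @return descending numeric vector of lambda values.
#' @export
lambda_grid <- function(spec, n_points = 20, min_ratio = 0.01,
                        standardize = TRUE) {
  if (n_points < 2) abort("n_points must be >= 2", class = "polyomics_error_value")
  null_fit <- fit_lasso_glmm(spec, lambda = Inf, standardize = standardize,
                             max_iter = 500)
  d <- build_design(spec, standardize = standardize)
  score <- drop(crossprod(d$Xp, d$y - null_fit$fitted))
  lam_max <- max(abs(score))
  if (!is.finite(lam_max) || lam_max <= 0) {
    abort("degenerate lambda grid: all features constant or uninformative",
          class = "polyomics_error_degenerate_grid")
  }
  # small headroom so the empty model at the top of the grid is robust to
  # the approximate convergence of the null mixed fit
  lam_max <- lam_max * 1.005
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_points))
}

#' Fit the penalty path
#'
#' Fits [fit_lasso_glmm()] sequentially from the largest lambda down, warm
#' starting each fit from the previous solution, and records the selected
#' feature set at every grid point. Per-lambda failures are recorded and
#' the path continues.
#'
#' @inheritParams fit_lasso_glmm
#' @param grid descending lambda grid from [lambda_grid()].
#' @param keep_fits retain the full `penalized_fit` objects as a list
#'   column.
#' @param max_selected stop extending the path once a fit selects more
#'   than this many features (denser models are beyond the scale the
#'   elbow rule targets and dominate runtime); `Inf` fits the whole grid.
#' @return a `lambda_path` tibble: `lambda`, `n_selected`, `selected`
#'   (list), `objective`, `converged` (and `fit` when `keep_fits`).
#' @export
lasso_path <- function(spec, grid, standardize = TRUE, keep_fits = FALSE,
                       tol = 1e-8, max_iter = 200, max_selected = Inf) {
  state <- NULL
  rows <- vector("list", length(grid))
  fits <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    fit <- tryCatch(
      fit_lasso_glmm(spec, grid[k], init = state, standardize = standardize,
                     tol = tol, max_iter = max_iter),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[k]] <- tibble::tibble(lambda = grid[k], n_selected = NA_integer_,
                                  selected = list(character(0)),
                                  objective = NA_real_, converged = FALSE,
                                  error = conditionMessage(fit))
      next
    }
    state <- fit$state
    if (keep_fits) fits[[k]] <- fit
    rows[[k]] <- tibble::tibble(lambda = grid[k],
                                n_selected = length(fit$selected),
                                selected = list(fit$selected),
                                objective = fit$objective,
                                converged = fit$converged,
                                error = NA_character_)
    if (length(fit$selected) > max_selected) {
      inform(sprintf(
        "path truncated at lambda %.4g: %d features selected (> %d)",
        grid[k], length(fit$selected), max_selected))
      rows <- rows[seq_len(k)]
      if (keep_fits) fits <- fits[seq_len(k)]
      break
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_fits) out$fit <- fits
  class(out) <- c("lambda_path", class(out))
  out
}

#' Pick the elbow of the selected-feature-count curve
#'
#' Orders the path by decreasing lambda and picks the interior grid point
#' maximizing the discrete downward curvature of the selected-count curve,
#' `2*c[k] - c[k-1] - c[k+1]` — the point where the count has just jumped
#' up and then flattens. Ties break toward larger lambda (the sparser
#' model). If no point has positive curvature (flat or linear count
#' curves), the point whose count is closest to half the maximum count is
#' used instead, with a warning.
#'
#' @param path a `lambda_path` from [lasso_path()].
#' @return the chosen lambda, with attributes `index` (grid position) and
#'   `fallback` (logical).
#' @export
select_lambda_elbow <- function(path) {
  path <- dplyr::arrange(path, dplyr::desc(.data$lambda))
  counts <- path$n_selected
  if (length(counts) < 3 || any(is.na(counts))) {
    abort("elbow selection needs >= 3 successfully fitted path points",
          class = "polyomics_error_value")
  }
  k <- 2:(length(counts) - 1)
  curvature <- 2 * counts[k] - counts[k - 1] - counts[k + 1]
  fallback <- all(curvature <= 0)
  if (!fallback) {
    idx <- k[which.max(curvature)]
  } else {
    warn("no elbow in selected-count curve; falling back to half-max count",
         class = "polyomics_warn_no_elbow")
    idx <- which.min(abs(counts - max(counts) / 2))
  }
  structure(path$lambda[idx], index = idx, fallback = fallback)
}

#' Unpenalized mixed-model refit on the selected features
#'
#' Refits the full mixed-effects logistic model (no penalty) on the
#' selected features plus the demographic covariates and random intercepts,
#' via `lme4::glmer`, yielding the feature weights used for risk scoring.
#' By default the fast `nAGQ = 0` (PIRLS) approximation is used — feature
#' weights differ negligibly from the full Laplace fit at a fraction of
#' the cost; set `nAGQ = 1` for the full Laplace likelihood. With no
#' usable grouping factors the model reduces to plain logistic regression
#' (`stats::glm`); on `glmer` failure the fit falls back down the chain
#' (Laplace, then `nAGQ = 0`, then `glm`), recording the engine used.
#'
#' @param data per-sample tibble (response, features, covariates, groups).
#' @param response 0/1 response column name.
#' @param features selected feature column names (empty yields the
#'   covariate-only model, with a warning).
#' @param covariates,random as in [mixed_model_spec()].
#' @param nAGQ integration points passed to `lme4::glmer` (0 or 1).
#' @return a `polyomic_refit`: underlying fit, `feature_coef` (named
#'   weights for scoring), full coefficient table, log-likelihood, engine.
#' @export
refit_glmm <- function(data, response, features,
                       covariates = c("age", "sex", "race", "antibiotic_use"),
                       random = c("site", "participant_id"), nAGQ = 0) {
  data <- tibble::as_tibble(data)
  if (!length(features)) {
    warn("no features selected; refitting covariate-only model",
         class = "polyomics_warn_no_features")
  }
  data <- dplyr::mutate(data, dplyr::across(dplyr::where(is.character), factor))
  usable_cov <- covariates[vapply(data[covariates],
                                  function(v) length(unique(v)) > 1, logical(1))]
  usable_rand <- random[vapply(data[random],
                               function(v) length(unique(v)) >= 2, logical(1))]
  bt <- function(v) sprintf("`%s`", v)
  fixed <- paste(c(bt(features), usable_cov, "1"), collapse = " + ")
  reterms <- paste(sprintf("(1 | %s)", usable_rand), collapse = " + ")

  engine <- if (nAGQ >= 1) "glmer" else "glmer_nAGQ0"
  fit <- NULL
  if (length(usable_rand)) {
    form <- stats::as.formula(paste(response, "~", fixed, "+", reterms))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(form, data = data, family = binomial(), nAGQ = nAGQ))),
      error = function(e) NULL
    )
    if (is.null(fit) || any(is.na(lme4::fixef(fit)))) {
      engine <- if (nAGQ >= 1) "glmer_nAGQ0" else "glmer"
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::glmer(form, data = data, family = binomial(),
                      nAGQ = 1 - (nAGQ >= 1)))),
        error = function(e) NULL
      )
    }
  }
  if (is.null(fit)) {
    engine <- "glm"
    form <- stats::as.formula(paste(response, "~", fixed))
    fit <- suppressWarnings(glm(form, data = data, family = binomial()))
  }

  fe <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  fe_clean <- setNames(fe, gsub("`", "", names(fe)))
  feature_coef <- fe_clean[features]
  feature_coef[is.na(feature_coef)] <- 0
  names(feature_coef) <- features

  structure(
    list(fit = fit, engine = engine, feature_coef = feature_coef,
         coefficients = fe_clean, loglik = as.numeric(logLik(fit)),
         n_obs = nrow(data), covariates = usable_cov, random = usable_rand,
         response = response),
    class = "polyomic_refit"
  )
}

#' @export
print.polyomic_refit <- function(x, ...) {
  cat(sprintf("<polyomic_refit (%s): %d feature weights, logLik = %.2f, n = %d>\n",
              x$engine, length(x$feature_coef), x$loglik, x$n_obs))
  invisible(x)
}
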