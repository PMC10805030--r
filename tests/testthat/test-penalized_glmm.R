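test_that("kernel solves weighted lasso exactly on an orthogonal design", {
  withr::with_seed(4, {
    n <- 64
    X <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))  # orthonormal columns
    z <- rnorm(n, sd = 2)
    lambda <- 0.4
    for (rep in 1:3) {
      beta0 <- rnorm(6)
      res <- polyomics:::wls_lasso_cd(X, z, rep(1, n), beta0,
                                      rep(1L, 6), lambda, 1e-12, 1000L)
      ols <- drop(crossprod(X, z))
      closed <- sign(ols) * pmax(abs(ols) - lambda, 0)
      expect_equal(drop(res$beta), closed, tolerance = 1e-10)
      z <- rnorm(n, sd = 2)
    }
  })
})

test_that("lambda = 0 with no grouping matches plain logistic regression", {
  for (seed in 1:3) {
    d <- solver_data(n = 150, p = 4, seed = seed)
    spec <- mixed_model_spec(d, "ibd", paste0("f", 1:4))
    fit <- fit_lasso_glmm(spec, lambda = 0)
    oracle <- glm(ibd ~ f1 + f2 + f3 + f4 + age + sex, data = d,
                  family = binomial())
    expect_equal(unname(fit$beta), unname(coef(oracle)[paste0("f", 1:4)]),
                 tolerance = 1e-4)
    expect_equal(unname(fit$covariate_coef["(Intercept)"]),
                 unname(coef(oracle)["(Intercept)"]), tolerance = 1e-4)
    expect_true(fit$converged)
  }
})

test_that("penalized objective is non-increasing over solver iterations", {
  d <- solver_data(n = 120, p = 6, seed = 8)
  spec <- mixed_model_spec(d, "ibd", paste0("f", 1:6))
  for (lam in c(0, 2, 10)) {
    fit <- fit_lasso_glmm(spec, lambda = lam)
    expect_true(all(diff(fit$obj_trace) <= 1e-8))
  }
})

test_that("solver agrees with glmnet at a fixed lambda (no random effects)", {
  skip_if_not_installed("glmnet")
  d <- solver_data(n = 200, p = 8, seed = 12)
  X <- as.matrix(d[paste0("f", 1:8)])
  spec <- mixed_model_spec(d[c("ibd", paste0("f", 1:8), "site", "participant_id")],
                           response = "ibd", features = paste0("f", 1:8),
                           covariates = character(0))
  lam <- 8
  fit <- fit_lasso_glmm(spec, lambda = lam, standardize = FALSE, tol = 1e-10)
  gn <- glmnet::glmnet(X, d$ibd, family = "binomial", alpha = 1,
                       lambda = lam / nrow(d), standardize = FALSE,
                       thresh = 1e-12)
  expect_equal(unname(fit$beta), unname(as.numeric(gn$beta)), tolerance = 5e-3)
})

test_that("lambda grid spans max-to-ratio and the top fit selects nothing", {
  d <- solver_data(n = 150, p = 5, seed = 2, grouped = TRUE)
  spec <- mixed_model_spec(d, "ibd", paste0("f", 1:5))
  grid <- lambda_grid(spec, n_points = 7, min_ratio = 0.05)
  expect_equal(length(grid), 7)
  expect_true(all(diff(grid) < 0))
  expect_equal(grid[7], grid[1] * 0.05, tolerance = 1e-10)
  top <- fit_lasso_glmm(spec, grid[1])
  expect_equal(length(top$selected), 0)

  g2 <- lambda_grid(spec, n_points = 2, min_ratio = 0.1)
  expect_equal(length(g2), 2)
  expect_equal(g2[2], g2[1] * 0.1, tolerance = 1e-10)
  expect_error(lambda_grid(spec, n_points = 1), class = "polyomics_error_value")

  # unstandardized lambda_max scales linearly with the feature columns
  d2 <- d
  d2[paste0("f", 1:5)] <- d2[paste0("f", 1:5)] * 2
  spec2 <- mixed_model_spec(d2, "ibd", paste0("f", 1:5))
  lm1 <- lambda_grid(spec, 3, 0.1, standardize = FALSE)[1]
  lm2 <- lambda_grid(spec2, 3, 0.1, standardize = FALSE)[1]
  expect_equal(lm2 / lm1, 2, tolerance = 1e-6)

  dc <- d
  dc[paste0("f", 1:5)] <- 1
  expect_error(lambda_grid(mixed_model_spec(dc, "ibd", paste0("f", 1:5)), 5),
               class = "polyomics_error_degenerate_grid")
})

test_that("warm-started path is coherent and at least as good as cold starts", {
  d <- solver_data(n = 180, p = 8, seed = 5, grouped = TRUE)
  spec <- mixed_model_spec(d, "ibd", paste0("f", 1:8))
  grid <- lambda_grid(spec, n_points = 8, min_ratio = 0.02)
  path <- lasso_path(spec, grid)
  expect_s3_class(path, "lambda_path")
  expect_equal(path$n_selected[1], 0)
  expect_gte(path$n_selected[8], path$n_selected[1])
  # warm-start objective no worse than a cold start, up to the wobble of
  # the approximate alternating solver (0.5% of the objective)
  for (k in c(3, 5, 8)) {
    cold <- fit_lasso_glmm(spec, grid[k])
    expect_lte(path$objective[k],
               cold$objective + max(1e-2, 0.005 * abs(cold$objective)))
  }
})

test_that("elbow selection maximizes curvature with sparser tie-break", {
  mk_path <- function(counts) {
    structure(tibble::tibble(
      lambda = rev(seq_along(counts)), n_selected = counts,
      selected = lapply(counts, function(k) sprintf("f%d", seq_len(k))),
      objective = 0, converged = TRUE
    ), class = c("lambda_path", class(tibble::tibble())))
  }
  p <- mk_path(c(0, 0, 1, 8, 9, 9, 9))
  lam <- select_lambda_elbow(p)
  expect_equal(attr(lam, "index"), 4L)             # the point with count 8
  expect_false(attr(lam, "fallback"))

  expect_warning(l2 <- select_lambda_elbow(mk_path(c(2, 2, 2, 2))),
                 class = "polyomics_warn_no_elbow")
  expect_true(attr(l2, "fallback"))
  expect_warning(l3 <- select_lambda_elbow(mk_path(c(0, 5, 10))),
                 class = "polyomics_warn_no_elbow")
  expect_true(attr(l3, "fallback"))
})

test_that("unpenalized refit matches glm without grouping and handles no features", {
  d <- solver_data(n = 150, p = 3, seed = 6)
  fit <- refit_glmm(d, "ibd", paste0("f", 1:3))
  expect_equal(fit$engine, "glm")  # single site/participant: no usable grouping
  oracle <- glm(ibd ~ f1 + f2 + f3 + age + sex, data = d, family = binomial())
  expect_equal(unname(fit$feature_coef), unname(coef(oracle)[paste0("f", 1:3)]),
               tolerance = 1e-4)

  expect_warning(cov_only <- refit_glmm(d, "ibd", character(0)),
                 class = "polyomics_warn_no_features")
  expect_equal(length(cov_only$feature_coef), 0)
  expect_true("(Intercept)" %in% names(cov_only$coefficients))
})

test_that("refit recovers its own generating coefficients within 2 SE", {
  withr::with_seed(17, {
    n <- 500
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    beta <- c(0.8, -0.8, 0.4, 0, 0, 0)
    y <- rbinom(n, 1, plogis(-0.2 + X %*% beta))
    d <- tibble::tibble(ibd = y, tibble::as_tibble(X),
                        age = rnorm(n, 30, 5),
                        sex = sample(c("female", "male"), n, TRUE),
                        race = "White", antibiotic_use = FALSE,
                        site = "s1", participant_id = "p1")
  })
  fit <- refit_glmm(d, "ibd", paste0("f", 1:6))
  sm <- summary(fit$fit)$coefficients
  est <- sm[paste0("f", 1:6), "Estimate"]
  se <- sm[paste0("f", 1:6), "Std. Error"]
  covered <- abs(est - beta) <= 2 * se
  expect_gte(mean(covered), 0.9)
})

test_that("elbow-selected model recovers planted support in a mixed cohort", {
  sim <- simulate_cohort(recovery_design(101))
  res <- suppressWarnings(fit_single_layer(sim, n_validation = 30))
  expect_gte(length(intersect(res$selected, res$causal)), 4)
})
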