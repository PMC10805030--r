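brute_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  pairs <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

test_that("AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  withr::with_seed(50, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      s <- rnorm(n)
      if (runif(1) < 0.3) s <- round(s)  # force ties sometimes
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "polyomics_error_evaluation")
})

test_that("large-sample null AUC is near one half and CI orders correctly", {
  withr::with_seed(51, {
    s <- rnorm(2000)
    y <- rbinom(2000, 1, 0.5)
  })
  r <- roc_auc(s, y)
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_lte(r$auc_lo, r$auc)
  expect_gte(r$auc_hi, r$auc)
})

test_that("OR per SD comes from logistic regression with Wald intervals", {
  withr::with_seed(52, {
    n <- 300
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.8 * s))
    covs <- data.frame(age = rnorm(n, 40, 10),
                       sex = sample(c("female", "male"), n, TRUE))
  })
  res <- or_per_sd(y, s, covs)
  oracle <- glm(y ~ s + age + sex, data = cbind(y = y, s = s, covs),
                family = binomial())
  expect_equal(res$or, exp(coef(oracle)[["s"]]), tolerance = 1e-10)
  se <- summary(oracle)$coefficients["s", "Std. Error"]
  expect_equal(res$or_lo, exp(coef(oracle)[["s"]] - 1.96 * se), tolerance = 1e-10)
  expect_true(res$or_lo <= res$or && res$or <= res$or_hi)

  # rescaling the score then re-standardizing leaves the OR per SD unchanged
  res2 <- or_per_sd(y, (2 * s - mean(2 * s)) / sd(2 * s), covs)
  res1 <- or_per_sd(y, (s - mean(s)) / sd(s), covs)
  expect_equal(res2$or, res1$or, tolerance = 1e-10)

  # separation flagged with unbounded CI
  expect_warning(sep <- or_per_sd(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12)),
                 class = "polyomics_warn_separation")
  expect_true(sep$separation)
  expect_equal(sep$or_hi, Inf)
})

test_that("null OR confidence intervals cover 1 at the nominal rate", {
  withr::with_seed(53, {
    hits <- vapply(1:200, function(i) {
      y <- rbinom(100, 1, 0.5)
      s <- rnorm(100)
      r <- suppressWarnings(or_per_sd(y, s))
      r$or_lo <= 1 && 1 <= r$or_hi
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("Nagelkerke R2 matches its defining formulas", {
  expect_equal(nagelkerke_r2(-10, -10, 20), 0)
  # perfect prediction: per-observation likelihood 1 => L1 = 0
  expect_equal(nagelkerke_r2(0, -log(2) * 50, 50), 1, tolerance = 1e-12)
  expect_error(nagelkerke_r2(-1, -2, 0), class = "polyomics_error_value")

  # 6-observation worked example against directly summed log-likelihoods
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(1, 2, 3, 2.5, 4, 5)
  fit <- glm(y ~ x, family = binomial())
  null <- glm(y ~ 1, family = binomial())
  l1 <- sum(dbinom(y, 1, fitted(fit), log = TRUE))
  l0 <- sum(dbinom(y, 1, fitted(null), log = TRUE))
  r2_cs <- 1 - exp(2 * (l0 - l1) / 6)
  expect_equal(nagelkerke_r2(l1, l0, 6), r2_cs / (1 - exp(2 * l0 / 6)),
               tolerance = 1e-12)
  expect_equal(nagelkerke_r2(as.numeric(logLik(fit)), as.numeric(logLik(null)), 6),
               nagelkerke_r2(l1, l0, 6), tolerance = 1e-10)
})

test_that("layer evaluation bundles AUC, OR and R2 with valid ranges", {
  withr::with_seed(54, {
    n <- 60
    d <- tibble::tibble(
      ibd = rbinom(n, 1, 0.5), age = rnorm(n, 35, 10),
      sex = sample(c("female", "male"), n, TRUE)
    )
    d$score <- 1.5 * d$ibd + rnorm(n)     # informative score
    d$null_score <- rnorm(n)
  })
  rep1 <- evaluate_layer(d, score = "score")
  expect_s3_class(rep1, "evaluation_report")
  expect_gt(rep1$auc, 0.7)
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  expect_gt(rep1$or, 1)
  expect_equal(rep1$n_cases + rep1$n_controls, n)

  rep0 <- evaluate_layer(d, score = "null_score")
  expect_lt(rep0$r2, 0.15)

  # score-only variant drops the covariates
  rep_so <- evaluate_layer(d, score = "score", covariates = character(0))
  oracle <- glm(ibd ~ score, data = d, family = binomial())
  expect_equal(rep_so$or, exp(coef(oracle)[["score"]]), tolerance = 1e-10)
})

test_that("combined model integrates independent signals and detects collinearity", {
  withr::with_seed(55, {
    n <- 400
    sc <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, OMIC_LAYERS))
    y <- rbinom(n, 1, plogis(0.8 * sc[, 1] + 0.8 * sc[, 2] +
                               0.8 * sc[, 3] + 0.8 * sc[, 4]))
    d <- tibble::tibble(ibd = y, tibble::as_tibble(sc),
                        age = rnorm(n, 35, 10),
                        sex = sample(c("female", "male"), n, TRUE))
  })
  res <- fit_combined(d)
  single_r2 <- vapply(OMIC_LAYERS, function(l) {
    evaluate_layer(d, score = l)$r2
  }, numeric(1))
  expect_gt(res$r2_full, max(single_r2))
  expect_true(all(res$cor_matrix[upper.tri(res$cor_matrix)] < 0.3))
  expect_equal(diag(res$cor_matrix), setNames(rep(1, 4), OMIC_LAYERS))

  # permuted labels: both R2s collapse
  d_perm <- d
  withr::with_seed(56, d_perm$ibd <- sample(d_perm$ibd))
  res_perm <- fit_combined(d_perm)
  expect_lt(res_perm$r2_full, 0.05)
  expect_lt(res_perm$r2_covariates, 0.05)

  # identical scores are flagged
  d_coll <- d
  d_coll$MTS <- d_coll$MGN
  d_coll$VRM <- d_coll$MGN
  d_coll$MBL <- d_coll$MGN
  expect_warning(fit_combined(d_coll), class = "polyomics_warn_collinear")

  expect_error(fit_combined(d[setdiff(names(d), "VRM")]),
               class = "polyomics_error_combined")
})

test_that("leave-one-omic-out respects nesting and ranks informative layers", {
  withr::with_seed(57, {
    n <- 300
    sc <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, OMIC_LAYERS))
    # strong MBL/VRM, weak MGN, null MTS
    y <- rbinom(n, 1, plogis(1.2 * sc[, "MBL"] + 1.2 * sc[, "VRM"] +
                               0.2 * sc[, "MGN"]))
    d <- tibble::tibble(ibd = y, tibble::as_tibble(sc),
                        age = rnorm(n, 35, 10),
                        sex = sample(c("female", "male"), n, TRUE))
  })
  loo <- leave_one_omic_out(d)
  full <- attr(loo, "full")
  expect_equal(sort(loo$omitted), sort(OMIC_LAYERS))
  expect_true(all(loo$loglik <= full$loglik + 1e-8))
  drop_null <- loo$delta_r2[loo$omitted == "MTS"]
  drop_strong <- loo$delta_r2[loo$omitted == "MBL"]
  expect_lt(drop_null, drop_strong)
})

test_that("co-occurrence matches direct correlation computation", {
  withr::with_seed(58, {
    m <- matrix(rnorm(25), 5, 5,
                dimnames = list(sprintf("s%d", 1:5), sprintf("f%d", 1:5)))
    m[, 2] <- -m[, 1]
  })
  tab <- omic_table(tibble::tibble(sample_id = rownames(m), tibble::as_tibble(m)),
                    "MGN", transform = "clr")
  cm <- cooccurrence(tab)
  expect_equal(unname(diag(cm)), rep(1, 5))
  expect_equal(cm["f1", "f2"], -1)
  direct <- cov(m) / outer(apply(m, 2, sd), apply(m, 2, sd))
  expect_equal(unname(cm), unname(direct), tolerance = 1e-12)
  expect_equal(cm, t(cm))

  m2 <- m
  m2[, 3] <- 7
  tab2 <- omic_table(tibble::tibble(sample_id = rownames(m2), tibble::as_tibble(m2)),
                     "MGN", transform = "clr")
  expect_warning(cm2 <- cooccurrence(tab2), class = "polyomics_warn_zero_variance")
  expect_true(all(is.na(cm2["f3", -3])))
})
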