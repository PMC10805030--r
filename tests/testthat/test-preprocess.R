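test_that("clr transform matches hand computation and zero-sum identity", {
  df <- tibble::tibble(sample_id = c("s1", "s2"),
                       f1 = c(1, 5), f2 = c(2, 5), f3 = c(4, 5))
  tab <- omic_table(df, "MGN")
  out <- clr_transform(tab, pseudocount = 0)
  # row (1,2,4): geometric mean 2 -> (ln 1/2, 0, ln 2)
  expect_equal(unname(ot_matrix(out)["s1", ]),
               c(log(0.5), 0, log(2)), tolerance = 1e-12)
  # uniform row maps to zero
  expect_equal(unname(ot_matrix(out)["s2", ]), c(0, 0, 0), tolerance = 1e-12)
  # zero-sum identity on random tables
  for (seed in 1:5) {
    t2 <- clr_transform(toy_table(seed = seed), pseudocount = 0.5)
    expect_true(all(abs(rowSums(ot_matrix(t2))) < 1e-10))
  }
  expect_error(clr_transform(out), class = "polyomics_error_state")
  expect_error(clr_transform(tab, -1), class = "polyomics_error_value")
  zero_tab <- omic_table(tibble::tibble(sample_id = "s1", f1 = 0, f2 = 1), "MGN")
  expect_error(clr_transform(zero_tab, 0), class = "polyomics_error_domain")
})

test_that("log10 transform is element-wise with pseudocount handling", {
  tab <- omic_table(tibble::tibble(sample_id = c("s1", "s2"),
                                   f1 = c(10, 1), f2 = c(100, 1000)), "MBL")
  out <- log10_transform(tab, pseudocount = 0)
  expect_equal(unname(ot_matrix(out)), matrix(c(1, 0, 2, 3), 2), tolerance = 1e-12)
  expect_equal(ot_transform(out), "log10")

  z <- omic_table(tibble::tibble(sample_id = "s1", f1 = 0), "MBL")
  expect_error(log10_transform(z, 0), class = "polyomics_error_domain")
  expect_equal(unname(ot_matrix(log10_transform(z, 1))["s1", ]), 0)
})

test_that("presence filter honours both boundary conventions on raw values", {
  # 20 samples, feature nonzero in exactly 1 (5%)
  m <- matrix(0, 20, 2, dimnames = list(sprintf("s%02d", 1:20), c("rare", "common")))
  m[1, "rare"] <- 3
  m[, "common"] <- 5
  tab <- omic_table(
    tibble::tibble(sample_id = rownames(m), tibble::as_tibble(m)), "VRM")
  res <- presence_filter(tab, 0.05, mode = "geq")
  expect_true("rare" %in% feature_ids(res$table))   # not "fewer than 5%"
  expect_equal(res$removed, character(0))

  # never-present feature removed under any positive threshold
  m[, "rare"] <- 0
  tab0 <- omic_table(tibble::tibble(sample_id = rownames(m), tibble::as_tibble(m)), "VRM")
  expect_equal(presence_filter(tab0, 0.01, "geq")$removed, "rare")

  # strict > rule: present in 99 of 100 removed, 100 of 100 retained
  m2 <- matrix(1, 100, 2, dimnames = list(sprintf("s%03d", 1:100), c("almost", "full")))
  m2[1, "almost"] <- 0
  tab2 <- omic_table(tibble::tibble(sample_id = rownames(m2), tibble::as_tibble(m2)), "MBL")
  res2 <- presence_filter(tab2, 0.99, mode = "gt")
  expect_equal(res2$removed, "almost")
  expect_equal(feature_ids(res2$table), "full")

  expect_error(presence_filter(tab2, 1.5), class = "polyomics_error_value")
})

test_that("collinearity filter removes one of each collinear pair, reproducibly", {
  withr::with_seed(42, {
    base <- rnorm(30)
    df <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                         A = base, B = base, C = base,
                         D = rnorm(30), E = rnorm(30))
  })
  tab <- omic_table(df, "MTS", transform = "clr")
  res <- collinearity_filter(tab, 0.95, seed = 3)
  # clique {A,B,C}: exactly one survivor, independent features untouched
  expect_equal(sum(c("A", "B", "C") %in% feature_ids(res$table)), 1)
  expect_true(all(c("D", "E") %in% feature_ids(res$table)))

  # identical seed -> identical removals; different seeds -> same count
  res_same <- collinearity_filter(tab, 0.95, seed = 3)
  expect_equal(res$removed, res_same$removed)
  counts <- vapply(1:5, function(s) {
    length(collinearity_filter(tab, 0.95, seed = s)$removed)
  }, numeric(1))
  expect_true(all(counts == counts[1]))

  # two independent features: nothing removed
  ind <- omic_table(tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                                   X = df$D, Y = df$E), "MTS", "clr")
  expect_equal(collinearity_filter(ind, 0.95, 1)$removed, character(0))
})

test_that("constant features are not removed by the collinearity filter", {
  df <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       flat = c(1, 1, 1), v = c(1, 2, 3))
  tab <- omic_table(df, "MTS", transform = "clr")
  res <- collinearity_filter(tab, 0.9, seed = 1)
  expect_equal(res$removed, character(0))
})

test_that("sd filter uses the n-1 denominator", {
  df <- tibble::tibble(sample_id = c("s1", "s2"),
                       flat = c(3, 3), spread = c(0, 2))
  tab <- omic_table(df, "MGN")
  res <- sd_filter(tab, min_sd = 1)
  expect_equal(res$removed, "flat")                 # SD 0 removed
  expect_true("spread" %in% feature_ids(res$table)) # sqrt(2) ~ 1.414 retained
  expect_equal(sd(c(0, 2)), sqrt(2))

  expect_equal(sd_filter(tab, 0)$removed, character(0))
  one <- omic_table(tibble::tibble(sample_id = "s1", f = 1), "MGN")
  expect_error(sd_filter(one, 1), class = "polyomics_error_state")
})

test_that("full recipe chains stages and filters are pure column subsets", {
  withr::with_seed(11, {
    # VRM-like: 20 of 23 features present in <5% of samples
    n <- 60
    m <- matrix(0, n, 23, dimnames = list(sprintf("s%02d", 1:n),
                                          sprintf("v%02d", 1:23)))
    for (j in 1:3) m[, j] <- rpois(n, 30)
    for (j in 4:23) m[sample(n, 2), j] <- rpois(2, 5)  # 2/60 ~ 3.3% < 5%
    tab <- omic_table(tibble::tibble(sample_id = rownames(m),
                                     tibble::as_tibble(m)), "VRM")
  })
  res <- suppressMessages(run_preprocess(tab))
  expect_s3_class(res$report, "filter_report")
  # sparse features eliminated by the presence stage
  expect_true(all(sprintf("v%02d", 4:23) %in%
                    unlist(res$report$removed[res$report$stage == "presence_geq_0.05"])))
  # stage chaining invariant
  k <- nrow(res$report)
  expect_equal(res$report$features_out[-k], res$report$features_in[-1])
  expect_equal(res$report$features_in,
               res$report$features_out + lengths(res$report$removed))
  # surviving columns bitwise identical to their transformed values
  full <- clr_transform(tab, 0.5)
  surv <- feature_ids(res$table)
  expect_identical(ot_matrix(res$table), ot_matrix(full)[, surv, drop = FALSE])

  # permissive thresholds leave everything in place
  cfg <- list(transform = "clr", pseudocount = 0.5,
              presence = list(threshold = 0, mode = "geq"),
              collinearity = 1, min_sd = 0, seed = 1)
  res2 <- suppressMessages(run_preprocess(tab, cfg))
  expect_true(all(res2$report$features_in == res2$report$features_out))
})
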