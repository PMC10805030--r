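#' Centered log-ratio transform
#'
#' Per-sample CLR for compositional count layers: each row `x` is replaced
#' by `ln((x + pc) / g(x + pc))` where `g` is the row geometric mean. Every
#' transformed row sums to zero.
#'
#' @param x a raw-count [omic_table()] (MGN/MTS/VRM).
#' @param pseudocount nonnegative count added before taking logs; must be
#'   positive when the table contains zeros.
#' @return the transformed `omic_table` (`transform = "clr"`).
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  if (ot_transform(x) != "raw") {
    abort("clr_transform expects a raw table", class = "polyomics_error_state")
  }
  if (pseudocount < 0) {
    abort("pseudocount must be >= 0", class = "polyomics_error_value")
  }
  m <- ot_matrix(x) + pseudocount
  if (any(m <= 0)) {
    abort("zero counts require a positive pseudocount",
          class = "polyomics_error_domain")
  }
  lm <- log(m)
  out <- lm - rowMeans(lm)
  ot_from_matrix(out, layer = ot_layer(x), transform = "clr")
}

#' Log10 transform for intensity layers
#'
#' @param x a raw [omic_table()] of intensities (MBL).
#' @param pseudocount nonnegative value added before `log10`.
#' @return the transformed `omic_table` (`transform = "log10"`).
#' @export
log10_transform <- function(x, pseudocount = 1) {
  if (ot_transform(x) != "raw") {
    abort("log10_transform expects a raw table", class = "polyomics_error_state")
  }
  if (pseudocount < 0) {
    abort("pseudocount must be >= 0", class = "polyomics_error_value")
  }
  m <- ot_matrix(x) + pseudocount
  if (any(m <= 0)) {
    abort("zero intensities require a positive pseudocount",
          class = "polyomics_error_domain")
  }
  ot_from_matrix(log10(m), layer = ot_layer(x), transform = "log10")
}

#' Presence (sparsity) filter
#'
#' Drops features observed in too few samples. Presence is always computed
#' on raw (pre-transform) nonzero entries — after CLR with a pseudocount no
#' zeros remain, so the raw table (or matrix) must be supplied when `x` is
#' already transformed. Two boundary conventions are supported:
#' `mode = "geq"` keeps features with presence fraction `>= threshold`
#' (the sparse-layer rule: features in *fewer than* 5% of samples removed),
#' `mode = "gt"` keeps presence `> threshold` (the near-complete rule:
#' keep compounds present in *more than* 99% of samples).
#'
#' @param x an [omic_table()].
#' @param threshold presence fraction in `[0, 1]`.
#' @param mode boundary convention, `"geq"` or `"gt"`.
#' @param raw raw-valued `omic_table` or matrix to compute presence on;
#'   defaults to `x` when `x` is raw.
#' @param fit_samples sample IDs used to compute presence fractions
#'   (default: all samples); the resulting feature list is applied to the
#'   whole table.
#' @return list with `table` (filtered) and `removed` (feature IDs).
#' @export
presence_filter <- function(x, threshold, mode = c("geq", "gt"), raw = NULL,
                            fit_samples = NULL) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) {
    abort("presence threshold must lie in [0, 1]", class = "polyomics_error_value")
  }
  rawm <- if (is.null(raw)) {
    if (ot_transform(x) != "raw") {
      abort("x is transformed; supply the raw table via `raw`",
            class = "polyomics_error_state")
    }
    ot_matrix(x)
  } else if (inherits(raw, "omic_table")) ot_matrix(raw) else raw
  rawm <- rawm[, feature_ids(x), drop = FALSE]
  if (!is.null(fit_samples)) rawm <- rawm[rownames(rawm) %in% fit_samples, , drop = FALSE]
  presence <- colMeans(rawm != 0)
  keep <- if (mode == "geq") presence >= threshold else presence > threshold
  subset_features(x, keep)
}

#' Collinearity filter
#'
#' Iteratively removes one member of any pair of features whose absolute
#' Pearson correlation exceeds `threshold`; the removed member of each pair
#' is chosen at random (seeded, reproducible). Zero-variance features are
#' treated as uncorrelated with everything and are never removed here.
#'
#' @param x a transformed [omic_table()] with at least 2 samples.
#' @param threshold correlation magnitude above which a pair is collinear.
#' @param seed RNG seed for the random member choice.
#' @param fit_samples sample IDs used to compute correlations (default all).
#' @return list with `table` and `removed`.
#' @export
collinearity_filter <- function(x, threshold = 0.95, seed = 1,
                                fit_samples = NULL) {
  m <- ot_matrix(x)
  if (!is.null(fit_samples)) m <- m[rownames(m) %in% fit_samples, , drop = FALSE]
  if (nrow(m) < 2) {
    abort("collinearity filter needs >= 2 samples", class = "polyomics_error_state")
  }
  cm <- suppressWarnings(cor(m))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  alive <- colnames(m)
  removed <- character(0)
  local_seed(seed, {
    repeat {
      a <- abs(cm)
      if (!length(a) || max(a) <= threshold) break
      hit <- which(a == max(a), arr.ind = TRUE)[1, ]
      drop_id <- alive[sample(c(hit[["row"]], hit[["col"]]), 1)]
      removed <- c(removed, drop_id)
      keep_idx <- alive != drop_id
      alive <- alive[keep_idx]
      cm <- cm[keep_idx, keep_idx, drop = FALSE]
    }
  })
  subset_features(x, !(feature_ids(x) %in% removed))
}

#' Standard-deviation filter
#'
#' Removes features whose sample SD (n-1 denominator), computed after
#' normalization, falls below `min_sd` — eliminating features with minimal
#' variation across samples.
#'
#' @param x a transformed [omic_table()] with at least 2 samples.
#' @param min_sd SD threshold; features with SD `< min_sd` are removed.
#' @param fit_samples sample IDs used to compute SDs (default all).
#' @return list with `table` and `removed`.
#' @export
sd_filter <- function(x, min_sd, fit_samples = NULL) {
  m <- ot_matrix(x)
  if (!is.null(fit_samples)) m <- m[rownames(m) %in% fit_samples, , drop = FALSE]
  if (nrow(m) < 2) {
    abort("sd_filter needs >= 2 samples (SD undefined)",
          class = "polyomics_error_state")
  }
  sds <- apply(m, 2, sd)
  subset_features(x, sds >= min_sd)
}

subset_features <- function(x, keep) {
  removed <- feature_ids(x)[!keep]
  tab <- x[c("sample_id", feature_ids(x)[keep])]
  list(table = omic_table(tab, layer = ot_layer(x), transform = ot_transform(x)),
       removed = removed)
}

#' Default per-layer preprocessing configuration
#'
#' Encodes the layer-specific normalization and filtering recipe:
#' \describe{
#'   \item{MGN}{CLR; SD filter at 1.0.}
#'   \item{MTS}{CLR; collinearity filter at 0.95; SD filter at 1.0.}
#'   \item{VRM}{CLR; presence filter keeping features found in at least 5%
#'     of samples (raw); SD filter at 0.1.}
#'   \item{MBL}{log10; presence filter keeping compounds present in more
#'     than 99% of samples (raw); collinearity filter at 0.95; SD filter at
#'     0.1.}
#' }
#'
#' @param layer layer tag.
#' @param seed seed for the collinearity filter's random member choice.
#' @return a named list config consumed by [run_preprocess()].
#' @export
default_layer_config <- function(layer, seed = 1) {
  layer <- match.arg(layer, OMIC_LAYERS)
  switch(layer,
    MGN = list(transform = "clr", pseudocount = 0.5, presence = NULL,
               collinearity = NULL, min_sd = 1.0, seed = seed),
    MTS = list(transform = "clr", pseudocount = 0.5, presence = NULL,
               collinearity = 0.95, min_sd = 1.0, seed = seed),
    VRM = list(transform = "clr", pseudocount = 0.5,
               presence = list(threshold = 0.05, mode = "geq"),
               collinearity = NULL, min_sd = 0.1, seed = seed),
    MBL = list(transform = "log10", pseudocount = 1,
               presence = list(threshold = 0.99, mode = "gt"),
               collinearity = 0.95, min_sd = 0.1, seed = seed)
  )
}

#' Run a layer's full preprocessing recipe
#'
#' Applies the configured stage sequence (normalize, then presence,
#' collinearity and SD filters as configured for the layer) and returns the
#' transformed, filtered table together with a stage-by-stage
#' `filter_report` tibble whose `features_out` of each stage equals the
#' `features_in` of the next. When `fit_samples` is given, all filter
#' statistics (presence fractions, correlations, SDs) are computed on those
#' samples only and the frozen feature list is applied to every sample —
#' the leakage-free default used by the pipeline.
#'
#' @param x a raw [omic_table()].
#' @param config layer config, see [default_layer_config()].
#' @param fit_samples optional sample IDs to fit filters on.
#' @return list with `table` (transformed + filtered) and `report`
#'   (a `filter_report` tibble).
#' @export
run_preprocess <- function(x, config = default_layer_config(ot_layer(x)),
                           fit_samples = NULL) {
  if (ot_transform(x) != "raw") {
    abort("run_preprocess expects a raw table", class = "polyomics_error_state")
  }
  raw <- x
  stages <- list()
  note <- function(name, n_in, n_out, removed) {
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = name, features_in = n_in, features_out = n_out,
      removed = list(removed)
    )
  }

  cur <- if (config$transform == "clr") {
    clr_transform(x, config$pseudocount)
  } else {
    log10_transform(x, config$pseudocount)
  }
  note(config$transform, length(feature_ids(x)), length(feature_ids(cur)), character(0))

  if (!is.null(config$presence)) {
    res <- presence_filter(cur, config$presence$threshold, config$presence$mode,
                           raw = raw, fit_samples = fit_samples)
    note(sprintf("presence_%s_%g", config$presence$mode, config$presence$threshold),
         length(feature_ids(cur)), length(feature_ids(res$table)), res$removed)
    cur <- res$table
  }
  if (!is.null(config$collinearity)) {
    res <- collinearity_filter(cur, config$collinearity, seed = config$seed,
                               fit_samples = fit_samples)
    note(sprintf("collinearity_%g", config$collinearity),
         length(feature_ids(cur)), length(feature_ids(res$table)), res$removed)
    cur <- res$table
  }
  if (!is.null(config$min_sd)) {
    res <- sd_filter(cur, config$min_sd, fit_samples = fit_samples)
    note(sprintf("sd_%g", config$min_sd),
         length(feature_ids(cur)), length(feature_ids(res$table)), res$removed)
    cur <- res$table
  }

  report <- dplyr::bind_rows(stages)
  report <- dplyr::mutate(report, layer = ot_layer(x), .before = 1)
  class(report) <- c("filter_report", class(report))
  inform(sprintf("%s: filtered from %d to %d features",
                 ot_layer(x), length(feature_ids(x)), length(feature_ids(cur))))
  list(table = cur, report = report)
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
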