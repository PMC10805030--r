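#' @useDynLib polyomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn inform .data
#' @importFrom stats sd var cor rnorm runif rbinom rmultinom logLik coef vcov
#'   plogis qlogis binomial glm predict setNames qnorm pnorm median
#' @importFrom utils head read.delim write.table
"_PACKAGE"

OMIC_LAYERS <- c("MGN", "MTS", "VRM", "MBL")
DIAGNOSIS_LEVELS <- c("nonIBD", "CD", "UC")

#' Construct an omic layer table
#'
#' An omic layer table is a tibble whose first column is `sample_id` and whose
#' remaining columns are numeric feature values for one omic layer, carrying
#' the layer tag (`MGN`, `MTS`, `VRM`, `MBL`) and the transform state (`raw`,
#' `clr`, `log10`) as attributes. Count layers (MGN/MTS/VRM) hold nonnegative
#' raw counts; the metabolomic layer (MBL) holds nonnegative ion intensities.
#'
#' @param x data frame with a `sample_id` column and numeric feature columns.
#' @param layer one of `"MGN"`, `"MTS"`, `"VRM"`, `"MBL"`.
#' @param transform transform state; `"raw"` for untransformed input.
#' @return a tibble of class `omic_table`.
#' @export
omic_table <- function(x, layer, transform = "raw") {
  layer <- match.arg(layer, OMIC_LAYERS)
  transform <- match.arg(transform, c("raw", "clr", "log10"))
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    abort("omic table needs a `sample_id` column", class = "polyomics_error_bad_table")
  }
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)
  feats <- setdiff(names(x), "sample_id")
  if (anyDuplicated(x$sample_id)) {
    abort(
      paste0("duplicate sample IDs: ",
             paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")),
      class = "polyomics_error_duplicate_ids"
    )
  }
  if (anyDuplicated(feats)) {
    abort("duplicate feature IDs", class = "polyomics_error_duplicate_ids")
  }
  is_num <- vapply(x[feats], is.numeric, logical(1))
  if (!all(is_num)) {
    abort(
      paste0("non-numeric feature columns: ", paste(feats[!is_num], collapse = ", ")),
      class = "polyomics_error_non_numeric"
    )
  }
  vals <- as.matrix(x[feats])
  if (length(vals) && any(!is.finite(vals))) {
    abort("feature values must be finite", class = "polyomics_error_bad_table")
  }
  if (transform == "raw" && length(vals) && any(vals < 0)) {
    abort("raw counts/intensities must be >= 0", class = "polyomics_error_bad_table")
  }
  structure(
    x,
    layer = layer,
    transform = transform,
    class = c("omic_table", class(tibble::tibble()))
  )
}

#' @export
print.omic_table <- function(x, ...) {
  cat(sprintf(
    "<omic_table: %s, %s, %d samples x %d features>\n",
    ot_layer(x), ot_transform(x), nrow(x), ncol(x) - 1L
  ))
  NextMethod()
}

#' Layer tag, transform state, IDs and matrix view of an omic table
#'
#' Accessors for the `omic_table` container: `ot_layer()` and `ot_transform()`
#' return the attributes, `feature_ids()`/`sample_ids()` the identifier
#' vectors, and `ot_matrix()` a samples-by-features numeric matrix with
#' sample IDs as row names.
#'
#' @param x an `omic_table`.
#' @return see individual descriptions.
#' @export
ot_layer <- function(x) attr(x, "layer")

#' @rdname ot_layer
#' @export
ot_transform <- function(x) attr(x, "transform")

#' @rdname ot_layer
#' @export
feature_ids <- function(x) setdiff(names(x), "sample_id")

#' @rdname ot_layer
#' @export
sample_ids <- function(x) x$sample_id

#' @rdname ot_layer
#' @export
ot_matrix <- function(x) {
  m <- as.matrix(x[feature_ids(x)])
  rownames(m) <- x$sample_id
  m
}

# rebuild a table from a matrix, keeping (or overriding) attributes
ot_from_matrix <- function(m, layer, transform) {
  df <- tibble::as_tibble(m)
  df <- dplyr::mutate(df, sample_id = rownames(m), .before = 1)
  omic_table(df, layer = layer, transform = transform)
}

#' Read a feature table from TSV
#'
#' Reads a tab-separated feature table into an [omic_table()]. The first
#' column holds identifiers; `orientation` declares whether rows are samples
#' (`"samples"`, the canonical internal orientation) or features
#' (`"features"`, transposed on read). All remaining cells must be numeric.
#'
#' @param path path to a UTF-8, tab-delimited file with a header row.
#' @param layer omic layer tag.
#' @param orientation `"samples"` if rows are samples, `"features"` if rows
#'   are features.
#' @return an `omic_table` with `transform = "raw"`.
#' @export
read_feature_table <- function(path, layer, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "polyomics_error_missing_file")
  }
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
  ids <- raw[[1]]
  cells <- raw[-1]
  num <- suppressWarnings(vapply(cells, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(cells)))
  if (any(is.na(num) & !is.na(as.matrix(cells)))) {
    bad <- which(is.na(num) & !is.na(as.matrix(cells)), arr.ind = TRUE)[1, ]
    abort(
      sprintf("non-numeric cell at row %d, column '%s'", bad[1], colnames(num)[bad[2]]),
      class = "polyomics_error_non_numeric"
    )
  }
  rownames(num) <- ids
  if (orientation == "features") num <- t(num)
  if (anyDuplicated(rownames(num)) || anyDuplicated(colnames(num))) {
    abort("duplicate sample or feature IDs in file", class = "polyomics_error_duplicate_ids")
  }
  ot_from_matrix(num, layer = layer, transform = "raw")
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()] (samples orientation): the round trip
#' preserves IDs and values.
#'
#' @param x an `omic_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate cohort metadata
#'
#' Reads a per-sample metadata TSV with the column contract
#' `sample_id`, `participant_id`, `diagnosis` (nonIBD/CD/UC, case-insensitive),
#' `age` (years), `sex` (female/male), `race`, `antibiotic_use`
#' (logical or yes/no), `site`, `week` (study week, >= 0). Missing `race`
#' cells map to an explicit `"unknown"` level so samples are never dropped
#' for an optional covariate. Every participant must carry a single
#' diagnosis across all of its samples.
#'
#' @param path metadata TSV path.
#' @return a validated metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "polyomics_error_missing_file")
  }
  df <- tibble::as_tibble(read.delim(path, sep = "\t", header = TRUE,
                                     check.names = FALSE, colClasses = "character"))
  as_cohort_metadata(df)
}

#' Validate a cohort metadata data frame
#'
#' @param df data frame following the [read_metadata()] column contract.
#' @return a validated metadata tibble with normalized types.
#' @export
as_cohort_metadata <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "participant_id", "diagnosis", "age", "sex",
                "race", "antibiotic_use", "site", "week")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("metadata missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "polyomics_error_bad_metadata")
  }
  dx <- normalize_level(df$diagnosis, DIAGNOSIS_LEVELS)
  sex <- normalize_level(df$sex, c("female", "male"))
  abx <- df$antibiotic_use
  if (!is.logical(abx)) {
    abx <- tolower(as.character(abx))
    map <- c("true" = TRUE, "false" = FALSE, "yes" = TRUE, "no" = FALSE,
             "1" = TRUE, "0" = FALSE)
    if (any(!abx %in% names(map))) {
      abort("unparseable antibiotic_use values", class = "polyomics_error_bad_level")
    }
    abx <- unname(map[abx])
  }
  race <- as.character(df$race)
  race[is.na(race) | race == ""] <- "unknown"
  out <- tibble::tibble(
    sample_id = as.character(df$sample_id),
    participant_id = as.character(df$participant_id),
    diagnosis = factor(dx, levels = DIAGNOSIS_LEVELS),
    age = as.numeric(df$age),
    sex = factor(sex, levels = c("female", "male")),
    race = race,
    antibiotic_use = abx,
    site = as.character(df$site),
    week = as.integer(round(as.numeric(df$week)))
  )
  if (anyDuplicated(out$sample_id)) {
    abort("duplicate sample_id in metadata", class = "polyomics_error_duplicate_ids")
  }
  if (any(!is.finite(out$age)) || any(out$age <= 0)) {
    abort("age must be a positive number", class = "polyomics_error_bad_metadata")
  }
  if (any(!is.finite(out$week)) || any(out$week < 0)) {
    abort("week must be >= 0", class = "polyomics_error_bad_metadata")
  }
  n_dx <- dplyr::summarise(dplyr::group_by(out, .data$participant_id),
                           n = dplyr::n_distinct(.data$diagnosis))
  bad <- n_dx$participant_id[n_dx$n > 1]
  if (length(bad)) {
    abort(
      paste0("participants with conflicting diagnoses: ", paste(bad, collapse = ", ")),
      class = "polyomics_error_diagnosis_conflict"
    )
  }
  out
}

normalize_level <- function(x, levels) {
  idx <- match(tolower(as.character(x)), tolower(levels))
  if (any(is.na(idx))) {
    abort(
      paste0("unknown level(s): ",
             paste(unique(x[is.na(idx)]), collapse = ", "),
             " (expected ", paste(levels, collapse = "/"), ")"),
      class = "polyomics_error_bad_level"
    )
  }
  levels[idx]
}

#' Binary IBD label from diagnosis
#'
#' CD and UC map to 1 (IBD present), nonIBD to 0.
#'
#' @param diagnosis factor or character vector of diagnoses.
#' @return integer 0/1 vector.
#' @export
ibd_label <- function(diagnosis) {
  as.integer(as.character(diagnosis) %in% c("CD", "UC"))
}

#' Align an omic table to cohort metadata
#'
#' Restricts the table to samples present in both the table and the metadata,
#' reordered to metadata order. Dropped sample IDs are reported via a
#' message. Alignment is idempotent.
#'
#' @param x an `omic_table`.
#' @param meta metadata tibble (see [read_metadata()]).
#' @param quiet suppress the dropped-sample message.
#' @return the aligned `omic_table`.
#' @export
align_samples <- function(x, meta, quiet = FALSE) {
  keep <- intersect(meta$sample_id, x$sample_id)
  if (!length(keep)) {
    abort("no samples shared between table and metadata",
          class = "polyomics_error_alignment")
  }
  dropped <- setdiff(x$sample_id, keep)
  if (length(dropped) && !quiet) {
    inform(sprintf("align_samples: dropped %d sample(s): %s",
                   length(dropped), paste(head(dropped, 10), collapse = ", ")))
  }
  out <- x[match(keep, x$sample_id), , drop = FALSE]
  omic_table(out, layer = ot_layer(x), transform = ot_transform(x))
}
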