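#' Read a KO identifier set
#'
#' One KEGG Orthology identifier (e.g. `K00001`) per line; blank lines and
#' `#` comments ignored. Duplicates are collapsed.
#'
#' @param path file path.
#' @return character vector of unique KO IDs.
#' @export
read_ko_set <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "polyomics_error_missing_file")
  }
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a compound-to-KO production map
#'
#' TSV with columns `compound_id` and `ko_id`: each row states that the KO
#' (a gene-function group) is annotated to a reaction producing the
#' compound.
#'
#' @param path file path.
#' @return tibble `compound_id`, `ko_id`.
#' @export
read_production_map <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "polyomics_error_missing_file")
  }
  df <- tibble::as_tibble(read.delim(path, sep = "\t", header = TRUE,
                                     colClasses = "character"))
  if (!all(c("compound_id", "ko_id") %in% names(df))) {
    abort("production map needs columns compound_id, ko_id",
          class = "polyomics_error_bad_table")
  }
  dplyr::distinct(df[c("compound_id", "ko_id")])
}

#' Collapse selected metabolite names to unique compound identifiers
#'
#' Annotated metabolite names can share a compound identifier (the same
#' molecule detected on different chromatography columns) or lack one
#' entirely; this de-duplicates mapped IDs and reports unmapped names
#' separately.
#'
#' @param mapping tibble/data frame with columns `name` and `compound_id`
#'   (`NA` or `""` for unmapped names).
#' @return list with `compounds` (unique mapped IDs, input order) and
#'   `unmapped` (names without an ID).
#' @export
collapse_compounds <- function(mapping) {
  mapping <- tibble::as_tibble(mapping)
  if (!all(c("name", "compound_id") %in% names(mapping))) {
    abort("mapping needs columns name, compound_id",
          class = "polyomics_error_bad_table")
  }
  id <- as.character(mapping$compound_id)
  unmapped <- mapping$name[is.na(id) | id == ""]
  list(compounds = unique(id[!is.na(id) & id != ""]),
       unmapped = as.character(unmapped))
}

#' Classify metabolite origins by KO-set logic
#'
#' For each compound, the producing KO set `P` from the production map is
#' intersected with the host KO set and the microbial KO sets (split into
#' taxa selected by the metagenomic model and the remaining detected taxa).
#' Host evidence means `P` hits the host set; microbial evidence means `P`
#' hits either taxa set. Categories: `host_only`, `microbe_only`,
#' `host_or_microbe`, and `other` (no producing KO in any provided set —
#' e.g. dietary compounds). Microbial evidence is sub-labelled
#' `selected_taxa`, `nonselected_taxa` or `both`. Compounds absent from
#' the map are treated as having an empty producing set.
#'
#' @param compounds character vector of compound IDs.
#' @param production_map tibble from [read_production_map()] (or a named
#'   list of KO vectors per compound).
#' @param host,selected,nonselected character vectors of KO IDs.
#' @return tibble `compound_id`, `category`, `microbe_evidence` (`NA` when
#'   no microbial evidence).
#' @export
classify_origins <- function(compounds, production_map, host,
                             selected = character(0),
                             nonselected = character(0)) {
  pmap <- if (is.data.frame(production_map)) {
    split(production_map$ko_id, production_map$compound_id)
  } else {
    production_map
  }
  purrr::map_dfr(compounds, function(cid) {
    P <- unique(pmap[[cid]] %||% character(0))
    host_hit <- length(intersect(P, host)) > 0
    sel_hit <- length(intersect(P, selected)) > 0
    non_hit <- length(intersect(P, nonselected)) > 0
    microbe_hit <- sel_hit || non_hit
    category <- if (host_hit && microbe_hit) "host_or_microbe"
      else if (host_hit) "host_only"
      else if (microbe_hit) "microbe_only"
      else "other"
    evidence <- if (sel_hit && non_hit) "both"
      else if (sel_hit) "selected_taxa"
      else if (non_hit) "nonselected_taxa"
      else NA_character_
    tibble::tibble(compound_id = cid, category = category,
                   microbe_evidence = evidence)
  })
}

#' Generate a toy KEGG-like fixture
#'
#' A small synthetic universe of KOs and compounds with a production map
#' and host/selected/non-selected KO sets, for tests and examples; it makes
#' the origin-classification module exercisable without any KEGG download.
#'
#' @param n_compounds number of compounds.
#' @param n_kos number of KO identifiers.
#' @param seed RNG seed.
#' @return list with `production_map` (tibble), `host`, `selected`,
#'   `nonselected` KO vectors, and `compounds`.
#' @export
toy_kegg_fixture <- function(n_compounds = 12, n_kos = 40, seed = 1) {
  local_seed(seed, {
    kos <- sprintf("K%05d", seq_len(n_kos))
    compounds <- sprintf("C%05d", seq_len(n_compounds))
    pm <- purrr::map_dfr(compounds, function(cid) {
      n <- sample(0:4, 1)
      if (n == 0) return(tibble::tibble(compound_id = character(0),
                                        ko_id = character(0)))
      tibble::tibble(compound_id = cid, ko_id = sample(kos, n))
    })
    k3 <- split(kos, sample(1:3, n_kos, replace = TRUE))
    list(production_map = pm, host = k3[["1"]] %||% character(0),
         selected = k3[["2"]] %||% character(0),
         nonselected = k3[["3"]] %||% character(0), compounds = compounds)
  })
}
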