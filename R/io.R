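#' Load a patient-level cost-effectiveness CSV
#'
#' Reads a comma-separated file with one row per subject and validates
#' it: the mapped effect/cost/arm columns must exist, contain no missing
#' values, and the arm column must be coded 0/1 with both arms present.
#' Columns are renamed to the standard `effect`, `cost`, `arm` names on
#' the way in.
#'
#' @param path Path to a CSV file with a header row.
#' @param effect,cost,arm Names of the corresponding columns in the
#'   file.
#' @param covariates Character vector of covariate column names to
#'   carry along (validated for missingness).
#' @param quiet Suppress the row/arm-count message.
#' @return A tibble with columns `effect`, `cost`, `arm` and the
#'   covariates, with attribute `"covariates"`.
#' @export
load_cea_csv <- function(path, effect = "effect", cost = "cost",
                         arm = "arm", covariates = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cea <- validate_cea(raw, effect, cost, arm, covariates)
  out <- tibble::tibble(effect = cea$effect, cost = cea$cost,
                        arm = cea$arm)
  if (length(covariates)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(cea$covariates))
  }
  attr(out, "covariates") <- covariates
  if (!quiet) {
    rlang::inform(sprintf(
      "loaded %d subjects (%d intervention, %d comparator) from %s",
      nrow(out), sum(out$arm == 1), sum(out$arm == 0), path
    ))
  }
  out
}

# Manifest written next to every CLI output so a run can be traced:
# command, options, seed, package version, timestamp, input checksum.
run_manifest <- function(command, options, seed, input = NULL) {
  list(
    command = command,
    options = options,
    seed = seed,
    package = "nbreg",
    version = as.character(utils::packageVersion("nbreg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_md5 = if (!is.null(input) && file.exists(input)) {
      unname(tools::md5sum(input))
    } else {
      NA_character_
    }
  )
}

write_manifest <- function(manifest, out_path) {
  jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
}
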