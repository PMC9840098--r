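# CSV and JSON plumbing shared by the command-line entry points. The CSV
# dialect is fixed: UTF-8, comma-separated, header row, RFC 4180 quoting —
# Japanese identifier text makes the explicit encoding non-negotiable.

#' Read / write person tables
#'
#' @param path CSV file path.
#' @param x data frame.
#' @return `read_person_csv` returns a data frame of character columns.
#' @export
read_person_csv <- function(path) {
  read.csv(path, colClasses = "character", check.names = FALSE,
           fileEncoding = "UTF-8")
}

#' @rdname read_person_csv
#' @export
write_person_csv <- function(x, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Write a linked pair to a directory
#'
#' Writes `screening.csv`, `registry.csv`, the ground-truth `truth.csv`,
#' the per-instance error audit `errors.csv` and a machine-readable
#' `manifest.json` recording the spec, seed and package version.
#'
#' @param pair a `pddi_pair`.
#' @param dir output directory (created if needed).
#' @export
write_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "pddi_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_person_csv(pair$screening, file.path(dir, "screening.csv"))
  write_person_csv(pair$registry, file.path(dir, "registry.csv"))
  write_person_csv(pair$truth, file.path(dir, "truth.csv"))
  write_person_csv(pair$errors, file.path(dir, "errors.csv"))
  spec <- pair$spec
  manifest <- list(
    label = spec$label, seed = spec$seed,
    n_screening = spec$n_screening, n_registry = spec$n_registry,
    n_common = spec$n_common, sex = spec$sex,
    plan = list(items = spec$plan$items, multi_key = spec$plan$multi_key,
                total = spec$plan$total),
    package = "pddi",
    version = as.character(utils::packageVersion("pddi")))
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_pair
#' @export
read_pair <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  truth <- read_person_csv(file.path(dir, "truth.csv"))
  truth$screening_row <- as.integer(truth$screening_row)
  truth$registry_row <- as.integer(truth$registry_row)
  plan <- if (length(manifest$plan$items) == 0 ||
              is.null(nrow(manifest$plan$items))) zero_error_plan()
          else error_plan(manifest$plan$items, manifest$plan$multi_key,
                          manifest$plan$total)
  spec <- dataset_spec(manifest$n_screening, manifest$n_registry,
                       manifest$n_common, label = manifest$label,
                       plan = plan, seed = manifest$seed,
                       sex = manifest$sex)
  structure(list(screening = read_person_csv(file.path(dir, "screening.csv")),
                 registry = read_person_csv(file.path(dir, "registry.csv")),
                 truth = truth,
                 errors = read_person_csv(file.path(dir, "errors.csv")),
                 spec = spec),
            class = "pddi_pair")
}

write_manifest <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             path, useBytes = TRUE)
  invisible(path)
}
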