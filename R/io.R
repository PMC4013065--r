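# Table I/O, configuration and run manifests.
#
# CSV dialect: comma-separated, UTF-8, "." decimal, mandatory header;
# descriptor columns use the canonical lower-case names.

#' Read a long-format descriptor table
#'
#' Required columns: `plant_id`, `ecotype`, `das`, and at least one
#' descriptor column (by default `area` must be present; pass
#' `required_descriptors` to tighten or relax). `das` is coerced to
#' numeric days; unknown columns are preserved untouched. Duplicate
#' `(plant_id, das)` rows and plants whose ecotype label varies are
#' rejected.
#'
#' @param path CSV file path.
#' @param required_descriptors descriptor columns that must be present.
#' @return a `data.frame`.
#' @export
read_descriptor_table <- function(path, required_descriptors = "area") {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_descriptor_table(d, required_descriptors)
}

validate_descriptor_table <- function(d, required_descriptors = "area") {
  need <- c("plant_id", "ecotype", "das", required_descriptors)
  for (col in need)
    if (!col %in% names(d)) stop("missing required column: ", col)
  d$das <- as.numeric(d$das)
  if (anyNA(d$das)) stop("`das` must be numeric days")
  key <- paste(d$plant_id, d$das)
  if (anyDuplicated(key))
    stop("duplicate (plant_id, das) row: ", key[duplicated(key)][1])
  eco_per_plant <- tapply(d$ecotype, d$plant_id,
                          function(e) length(unique(e)))
  if (any(eco_per_plant > 1L))
    stop("ecotype must be constant within plant_id: ",
         names(eco_per_plant)[eco_per_plant > 1L][1])
  d
}

#' Write results to CSV or JSON
#'
#' Data frames go to CSV with a stable column order (metadata columns
#' first, then descriptors in canonical order, then the rest); lists go
#' to JSON. Refuses to overwrite an existing file unless `force = TRUE`.
#'
#' @param obj a `data.frame` or a list.
#' @param path destination (`.csv` or `.json`).
#' @param force overwrite an existing file.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("file exists (use force = TRUE to overwrite): ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.data.frame(obj)) {
    if (ext != "csv") stop("data frames are written as .csv")
    meta <- intersect(c("plant_id", "ecotype", "das", "mid_das"),
                      names(obj))
    desc <- intersect(descriptor_names(), names(obj))
    rest <- setdiff(names(obj), c(meta, desc))
    utils::write.csv(obj[, c(meta, desc, rest), drop = FALSE], path,
                     row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("unsupported output format: .", ext)
  invisible(path)
}

#' Run manifest
#'
#' A JSON-serialisable record of a pipeline invocation: command,
#' parameters, seed, timestamp, package version, and md5 checksums of the
#' input and output files, supporting reproducible re-runs.
#'
#' @param command character label of the stage.
#' @param parameters named list of parameters.
#' @param seed integer seed used (or `NA`).
#' @param inputs,outputs file paths to checksum (missing files are
#'   recorded as `NA`).
#' @return a list of class `run_manifest`.
#' @export
run_manifest <- function(command, parameters = list(), seed = NA_integer_,
                         inputs = character(0), outputs = character(0)) {
  sums <- function(paths) {
    if (!length(paths)) return(NULL)
    s <- vapply(paths, function(p)
      if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
      character(1))
    as.list(s)
  }
  structure(list(command = command, parameters = parameters, seed = seed,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 version = as.character(utils::packageVersion("phenorosette")),
                 input_checksums = sums(inputs),
                 output_checksums = sums(outputs)),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON destination.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a YAML or JSON configuration file
#'
#' Configuration files mirror the CLI flags; explicit flags override
#' config values.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
}
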