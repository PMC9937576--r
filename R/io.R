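#' Load a parameter configuration
#'
#' Reads a flat key-value config file (YAML or JSON, by file extension)
#' holding the model parameter fields (`k`, `n`, `e`, `c_c`, `c_h`,
#' `b_CG`, `b_PG`, `b_h`, `p`, `mu`); missing fields fall back to the
#' two-group baseline defaults of [model_params()]. Parameters are
#' validated at load; a violated dilemma condition is reported with the
#' specific inequality that failed.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [model_params()] object; any non-parameter keys in
#'   the file are attached as attribute `"extra"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)"))
  known <- intersect(param_fields, names(raw))
  pars <- do.call(model_params, raw[known])
  extra <- raw[setdiff(names(raw), param_fields)]
  if (length(extra)) attr(pars, "extra") <- extra
  pars
}

#' Save a parameter configuration
#'
#' Writes the parameter fields as a flat key-value file; round-trips
#' losslessly through [load_config()].
#'
#' @param params A [model_params()] object.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  pars <- as_coop_params(params, check = FALSE)
  x <- pars[param_fields]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: .", ext, " (use YAML or JSON)"))
  invisible(path)
}

#' Build an experiment manifest
#'
#' A manifest ties a result file to everything needed to regenerate it:
#' the parameter set, grid definitions, seeds, the engine used, the package
#' version, the state-enumeration order tag, and a timestamp.
#'
#' @param params A [model_params()] object.
#' @param engine `"exact"` or `"abm"`.
#' @param seed Integer seed (or `NA`).
#' @param grids Optional named list of grid vectors (e.g. `p`, `b_h`).
#' @param backend Optional solver backend tag.
#' @param notes Optional free-text notes.
#' @return List of class `"coop_manifest"`.
#' @export
experiment_manifest <- function(params, engine = c("exact", "abm"),
                                seed = NA_integer_, grids = NULL,
                                backend = NULL, notes = NULL) {
  pars <- as_coop_params(params, check = FALSE)
  structure(list(
    engine = match.arg(engine),
    params = unclass(pars)[param_fields],
    grids = grids,
    seed = seed,
    backend = backend,
    enumeration_order = "lexicographic",
    package_version = as.character(utils::packageVersion("coopevo")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    notes = notes), class = "coop_manifest")
}

#' Write a result table with its manifest
#'
#' Writes the data as CSV (comma-separated, UTF-8, `.` decimal, header row)
#' with at least 15 significant digits, and the manifest as a JSON sidecar
#' `<path without extension>_manifest.json`.
#'
#' @param table `data.frame` of results.
#' @param manifest A `"coop_manifest"` from [experiment_manifest()].
#' @param path Output CSV path.
#' @return Named character vector with the two paths written, invisibly.
#' @export
write_results <- function(table, manifest, path) {
  stopifnot(is.data.frame(table), inherits(manifest, "coop_manifest"))
  tab <- table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 15, trim = TRUE))
  })
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("failed writing results to '", path, "': ",
                              conditionMessage(e)))
  mpath <- paste0(tools::file_path_sans_ext(path), "_manifest.json")
  jsonlite::write_json(unclass(manifest), mpath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(data = path, manifest = mpath))
}

#' Read back a result table and its manifest
#'
#' @param path CSV path written by [write_results()].
#' @return `data.frame` with the manifest (if present) attached as
#'   attribute `"manifest"`.
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  mpath <- paste0(tools::file_path_sans_ext(path), "_manifest.json")
  if (file.exists(mpath)) {
    attr(tab, "manifest") <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  }
  tab
}
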