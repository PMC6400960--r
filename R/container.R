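FLICS_SCHEMA_VERSION <- "1.0"

#' Write scenes and measurements to a dataset container
#'
#' Single-file, schema-versioned container (base-R serialization) pairing
#' ground-truth scenes with their measurements atomically. Every measurement
#' must reference an existing scene id. Round-trips arrays bit-exactly.
#'
#' @param path output file path.
#' @param scenes list of [lifetime_scene()] objects.
#' @param measurements optional named list of `measurement_set` objects; names
#'   are scene ids.
#' @param meta optional list of run metadata (config hash, seeds, ...).
#' @param overwrite overwrite an existing file (default `FALSE`).
#' @return invisibly, `path`.
#' @export
write_dataset <- function(path, scenes, measurements = NULL, meta = list(),
                          overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("file exists: ", path, " (use overwrite = TRUE)")
  ids <- vapply(scenes, function(s) s$scene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate scene ids")
  if (!is.null(measurements)) {
    mids <- names(measurements)
    if (is.null(mids) || any(mids == ""))
      stop("measurements must be a named list keyed by scene id")
    missing_ids <- setdiff(mids, ids)
    if (length(missing_ids))
      stop("measurement(s) reference unknown scene id(s): ",
           paste(missing_ids, collapse = ", "))
    for (m in measurements) stopifnot(inherits(m, "measurement_set"))
  }
  for (s in scenes) stopifnot(inherits(s, "lifetime_scene"))
  obj <- list(schema_version = FLICS_SCHEMA_VERSION,
              created = format(Sys.time(), tz = "UTC"),
              meta = meta, scene_ids = ids,
              scenes = stats::setNames(scenes, ids),
              measurements = measurements)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a dataset container
#'
#' Validates the schema version and object classes; a truncated or foreign
#' file yields a clean error, never partial objects.
#'
#' @param path file written by [write_dataset()].
#' @return list with `scenes` (named list, stored order), `measurements`
#'   (named list or `NULL`), `meta`, `scene_ids`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable dataset file '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$schema_version))
    stop("'", path, "' is not a flics dataset container")
  if (!identical(obj$schema_version, FLICS_SCHEMA_VERSION))
    stop("dataset schema version ", obj$schema_version,
         " not supported (this build reads ", FLICS_SCHEMA_VERSION, ")")
  for (s in obj$scenes) stopifnot(inherits(s, "lifetime_scene"))
  obj[c("scenes", "measurements", "meta", "scene_ids")]
}
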