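# All coordinates and measurements are millimetres throughout; the only unit
# handling is the bounding-box sanity warning in load_case().

#' Read a landmark file
#'
#' JSON object mapping the five canonical landmark names to `[x, y, z]`
#' arrays in mm. Unknown keys are rejected unless `allow_extra = TRUE`.
#'
#' @param path Path to the JSON file.
#' @param allow_extra Allow (and ignore) non-canonical keys.
#' @return A `vm_landmarks`.
#' @export
read_landmarks <- function(path, allow_extra = FALSE) {
  if (!file.exists(path)) .vm_stop("vm_io", "landmark file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(landmark_names(), names(obj))
  if (length(missing))
    .vm_stop("vm_schema", "landmark file is missing required key(s): %s",
             paste(missing, collapse = ", "))
  extra <- setdiff(names(obj), landmark_names())
  if (length(extra) && !allow_extra)
    .vm_stop("vm_schema", "unknown landmark key(s): %s (use allow_extra to ignore)",
             paste(extra, collapse = ", "))
  do.call(landmark_set, obj[landmark_names()])
}

#' Write a landmark file
#'
#' @param lm A `vm_landmarks`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "vm_landmarks"))
  jsonlite::write_json(unclass(lm), path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a measurement case
#'
#' @param mesh_path Mesh file (STL/PLY/OBJ, mm).
#' @param landmarks_path Landmark JSON file.
#' @param specimen_id Specimen identifier.
#' @param level Vertebral level, one of C3..C7 (or NA).
#' @param allow_extra Passed to [read_landmarks()].
#' @return A `vm_case` list with `specimen_id`, `level`, `mesh`, `landmarks`.
#'   Warns when the mesh bounding box is below 5 mm or above 500 mm (likely
#'   unit error).
#' @export
load_case <- function(mesh_path, landmarks_path, specimen_id = "specimen",
                      level = NA_character_, allow_extra = FALSE) {
  if (!is.na(level) && !level %in% c("C3", "C4", "C5", "C6", "C7"))
    .vm_stop("vm_schema", "level must be one of C3..C7")
  mesh <- read_mesh(mesh_path)
  lm <- read_landmarks(landmarks_path, allow_extra = allow_extra)
  ext <- max(apply(mesh$vertices, 2, function(v) diff(range(v))))
  if (ext < 5 || ext > 500)
    warning(sprintf("mesh bounding box extent %.3g mm: check that units are mm", ext))
  structure(list(specimen_id = specimen_id, level = level,
                 mesh = mesh, landmarks = lm),
            class = "vm_case")
}

# fixed 6-significant-digit formatting keeps CSV outputs diffable
.vm_fmt <- function(x) {
  ifelse(is.na(x), "", sprintf("%.6g", x))
}

.vm_write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .vm_fmt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write measurement records to CSV
#'
#' One row per plane label with the positional columns `SED_mm`, `IECD_mm`,
#' `IED_mm` and the conventional alias name of each value (`LSED` ... `RIED`).
#' Numbers are written with 6 significant digits so outputs are diffable.
#'
#' @param records A `vm_measurements` data frame.
#' @param path Output CSV path.
#' @param specimen_id,level Identification columns.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, specimen_id = "specimen",
                               level = NA_character_) {
  stopifnot(inherits(records, "data.frame"))
  if (nrow(records) == 0) specimen_id <- level <- character(0)
  df <- data.frame(specimen_id = specimen_id, level = level,
                   label = records$label,
                   SED_mm = records$sed_mm,
                   IECD_mm = records$iecd_mm,
                   IED_mm = records$ied_mm,
                   SED_alias = measurement_alias(records$label, "SED"),
                   IECD_alias = measurement_alias(records$label, "IECD"),
                   IED_alias = measurement_alias(records$label, "IED"),
                   stringsAsFactors = FALSE)
  .vm_write_csv(df, path)
}

#' Read measurement records written by [write_measurements()]
#'
#' @param path CSV path.
#' @return A `vm_measurements` data frame (columns `label`, `sed_mm`,
#'   `iecd_mm`, `ied_mm`), with `specimen_id` and `level` as attributes.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(label = df$label, sed_mm = df$SED_mm,
                    iecd_mm = df$IECD_mm, ied_mm = df$IED_mm,
                    stringsAsFactors = FALSE)
  attr(out, "specimen_id") <- df$specimen_id[1]
  attr(out, "level") <- df$level[1]
  class(out) <- c("vm_measurements", "data.frame")
  out
}

#' Write a reliability table to CSV
#'
#' @param table A `vm_reliability_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  .vm_write_csv(as.data.frame(table), path)
}

#' Write a simulated study dataset to CSV (long format)
#'
#' @param data Long-format study data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(data, path) {
  .vm_write_csv(data, path)
}

#' Read a long-format study dataset
#'
#' @param path CSV with columns `specimen_id`, `level`, `dimension`,
#'   `session`, `value_mm` (a `sex` column is allowed and kept).
#' @return Data frame.
#' @export
read_study <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "level", "dimension", "session", "value_mm")
  if (!all(req %in% names(df)))
    .vm_stop("vm_schema", "study CSV is missing column(s): %s",
             paste(setdiff(req, names(df)), collapse = ", "))
  df
}

#' Run provenance log
#'
#' Records the tool version, the MD5 digest of every input file, the seed,
#' and per-stage timings/warnings, as a JSON sidecar next to an output file.
#'
#' @param output_path The output file the log describes (`<output>.log.json`
#'   is written).
#' @param inputs Character vector of input file paths.
#' @param seed Seed used (or NA).
#' @param stages Optional named list of stage timings (seconds) or notes.
#' @return Path of the log file, invisibly.
#' @export
write_run_log <- function(output_path, inputs = character(), seed = NA,
                          stages = list()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  log <- list(tool = "vertamorph",
              version = as.character(utils::packageVersion("vertamorph")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, input_digests = digests, stages = stages)
  path <- paste0(output_path, ".log.json")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
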