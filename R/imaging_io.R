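# NIfTI volume and CSV manifest input/output with validation.  Volumes are
# assumed pre-aligned on a common grid (registration is upstream of this
# package); no reorientation is performed and the on-disk axis order is
# kept.  Malformed inputs are rejected, never silently repaired.

MANIFEST_MANDATORY <- c("participant_id", "timepoint", "age", "sex",
                        "scanner")
MANIFEST_KNOWN <- c(MANIFEST_MANDATORY, "icv", "education_college",
                    "apoe_e4", "health_status", "interval", "split",
                    RISK_FACTORS, COG_TESTS,
                    paste0("path_", MAP_LABELS))

#' Write the five volumes of a map set as NIfTI files
#'
#' Files are named `<participant_id>_<timepoint>_<map>.nii.gz` with an
#' identity-scaled affine.
#'
#' @param map_set a `dwi_map_set` (see [render_maps()]).
#' @param dir output directory.
#' @return named list of the five file paths, in FA/MD/AxD/RD/MO order.
#' @export
write_map_set <- function(map_set, dir) {
  stopifnot(inherits(map_set, "dwi_map_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(MAP_LABELS, function(m) {
    p <- file.path(dir, sprintf("%s_%s_%s.nii.gz", map_set$participant_id,
                                map_set$timepoint, m))
    RNifti::writeNifti(RNifti::asNifti(map_set$volumes[[m]]), p)
    p
  })
  setNames(paths, MAP_LABELS)
}

#' Load the five aligned volumes referenced by one manifest row
#'
#' All five maps must be present, share a common grid, and contain no
#' NaN/Inf voxels; violations are rejected with an error naming the
#' offending map.
#'
#' @param manifest_row a one-row data.frame (or named list) carrying
#'   `participant_id`, `timepoint` and the five `path_<map>` columns.
#' @return a `dwi_map_set` with voxels cast to double.
#' @export
load_map_set <- function(manifest_row) {
  row <- as.list(manifest_row)
  for (m in MAP_LABELS) {
    p <- row[[paste0("path_", m)]]
    if (is.null(p) || is.na(p) || !nzchar(p))
      stop_wm("manifest row for %s is missing the %s map",
              row$participant_id %||% "<unknown>", m)
    if (!file.exists(p))
      stop_wm("%s map file does not exist: %s", m, p)
  }
  vols <- lapply(MAP_LABELS, function(m) {
    v <- as.array(RNifti::readNifti(row[[paste0("path_", m)]]))
    storage.mode(v) <- "double"
    if (length(dim(v)) != 3)
      stop_wm("%s map is not a 3D volume", m)
    if (any(!is.finite(v)))
      stop_wm("%s map contains NaN/Inf voxels", m)
    v
  })
  names(vols) <- MAP_LABELS
  shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop_wm("maps disagree on grid shape: %s",
            paste(sprintf("%s=%s", names(shapes), shapes), collapse = ", "))
  structure(list(participant_id = row$participant_id,
                 timepoint = row$timepoint,
                 grid_shape = dim(vols[[1]]), volumes = vols),
            class = "dwi_map_set")
}

#' Write a participant manifest as CSV
#'
#' Missing values are encoded as empty cells; sex is female = 0 / male = 1
#' and scanner is an integer site code in `{0, 1, 2}`.
#'
#' @param records data.frame of participant records (optionally with map
#'   path columns from [render_cohort_maps()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  missing_cols <- setdiff(MANIFEST_MANDATORY, names(records))
  if (length(missing_cols))
    stop_wm("manifest lacks mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a participant manifest
#'
#' Mandatory columns must be present; unknown columns are kept but warned
#' about; duplicate participant-timepoint combinations are rejected.  If
#' path columns are present, every referenced file must exist.  An empty
#' (header-only) file yields an empty manifest without error.
#'
#' @param path CSV path written by [write_manifest()].
#' @param check_paths verify that referenced map files exist.
#' @return data.frame of records.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character"))
  missing_cols <- setdiff(MANIFEST_MANDATORY, names(df))
  if (length(missing_cols))
    stop_wm("manifest lacks mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(df), MANIFEST_KNOWN)
  if (length(unknown))
    warning(sprintf("manifest has unknown column(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0) return(df)
  key <- paste(df$participant_id, df$timepoint)
  if (anyDuplicated(key))
    stop_wm("duplicate participant_id x timepoint in manifest: %s",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  df$timepoint <- as.character(df$timepoint)
  pcols <- intersect(paste0("path_", MAP_LABELS), names(df))
  if (check_paths && length(pcols)) {
    for (p in pcols) {
      gone <- !file.exists(df[[p]])
      if (any(gone))
        stop_wm("manifest references missing file(s), e.g. %s",
                df[[p]][which(gone)[1]])
    }
  }
  df
}
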