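# Synthetic phantom rendering: each of the five diffusion-map analogues is
# a sum of a fixed smooth spatial template, an age-dependent amplitude term
# driven by effective age (chronological age + true gap), a participant-
# level shared field (correlating the five maps), and i.i.d. voxel noise.
# No anatomical realism is attempted; only a spatially structured, monotone
# (or, for the MO analogue, non-monotone) age signal is needed.

# deterministic blob centres/widths per map (fractions of the grid); these
# are part of the phantom definition, not of the random stream
.map_blob_table <- list(
  FA  = list(c(0.35, 0.40, 0.50, 0.18), c(0.70, 0.55, 0.45, 0.22)),
  MD  = list(c(0.50, 0.30, 0.40, 0.20), c(0.30, 0.70, 0.60, 0.18)),
  AxD = list(c(0.60, 0.50, 0.35, 0.22), c(0.40, 0.35, 0.70, 0.17)),
  RD  = list(c(0.45, 0.65, 0.55, 0.19), c(0.65, 0.25, 0.35, 0.21)),
  MO  = list(c(0.30, 0.55, 0.65, 0.20), c(0.55, 0.60, 0.30, 0.19)))
.shared_blob <- c(0.5, 0.5, 0.5, 0.35)

.template_cache <- new.env(parent = emptyenv())

gauss_blob <- function(grid, spec) {
  ax <- lapply(1:3, function(k) {
    u <- (seq_len(grid[k]) - 0.5) / grid[k]
    exp(-((u - spec[k])^2) / (2 * spec[4]^2))
  })
  outer(outer(ax[[1]], ax[[2]]), ax[[3]])
}

map_templates <- function(grid) {
  key <- paste(grid, collapse = "x")
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  tpl <- lapply(MAP_LABELS, function(m) {
    blobs <- .map_blob_table[[m]]
    P0 <- 1 + 0.3 * gauss_blob(grid, blobs[[1]])
    W <- 0.4 + 1.5 * gauss_blob(grid, blobs[[2]])
    W <- W / mean(W)  # unit mean so the voxel-mean age slope is the config slope
    list(P0 = P0, W = W)
  })
  names(tpl) <- MAP_LABELS
  out <- list(maps = tpl, S = gauss_blob(grid, .shared_blob))
  .template_cache[[key]] <- out
  out
}

#' Render the five synthetic diffusion-map volumes for one participant
#'
#' Voxel intensities are smooth deterministic functions of the effective
#' age (chronological age + true gap): the FA analogue decreases with age,
#' the MD/AxD/RD analogues increase, and the MO analogue follows a concave
#' quadratic, plus a participant-level field shared across the five maps
#' and i.i.d. Gaussian voxel noise.  Rendering is deterministic given the
#' configuration seed and participant id.
#'
#' @param record one-row data.frame for a participant-timepoint.
#' @param truth matching one-row ground-truth data.frame.
#' @param config a [synth_config()].
#' @return an object of class `dwi_map_set`: participant id, timepoint,
#'   grid shape, and the named list of five 3D arrays.
#' @export
render_maps <- function(record, truth, config) {
  if (nrow(record) != 1 || nrow(truth) != 1)
    stop_wm("render_maps expects exactly one record and one truth row")
  if (!identical(record$participant_id, truth$participant_id))
    stop_wm("record and truth participant ids differ (%s vs %s)",
            record$participant_id, truth$participant_id)
  grid <- config$grid_shape
  tpl <- map_templates(grid)
  eff <- record$age + truth$true_gap
  da <- eff - config$map_ref_age
  label <- paste0("maps:", record$participant_id, ":", record$timepoint)
  vols <- with_seed(config$seed, label, {
    subj <- rnorm(1, 0, config$subject_field_sd)
    out <- lapply(MAP_LABELS, function(m) {
      t0 <- tpl$maps[[m]]
      v <- config$map_baselines[[m]] * t0$P0 +
        (config$map_age_slopes[[m]] * da +
           config$map_quads[[m]] * da^2) * t0$W +
        subj * tpl$S
      if (config$noise_sd_map[[m]] > 0)
        v <- v + array(rnorm(prod(grid), 0, config$noise_sd_map[[m]]), grid)
      v
    })
    names(out) <- MAP_LABELS
    out
  })
  structure(list(participant_id = record$participant_id,
                 timepoint = record$timepoint,
                 grid_shape = grid, volumes = vols),
            class = "dwi_map_set")
}

#' Render and write all maps for a cohort, returning a manifest
#'
#' Calls [render_maps()] for every record, writes each volume as a NIfTI
#' file named `<participant_id>_<timepoint>_<map>.nii.gz`, and returns the
#' records with one path column per map appended.
#'
#' @param records,truth matching data.frames from [simulate_cohort()].
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (records plus `path_FA` .. `path_MO`).
#' @export
render_cohort_maps <- function(records, truth, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- matrix(NA_character_, nrow(records), 5,
                  dimnames = list(NULL, paste0("path_", MAP_LABELS)))
  for (i in seq_len(nrow(records))) {
    ms <- render_maps(records[i, , drop = FALSE], truth[i, , drop = FALSE],
                      config)
    paths[i, ] <- unlist(write_map_set(ms, dir))
  }
  cbind(records, as.data.frame(paths, stringsAsFactors = FALSE))
}
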