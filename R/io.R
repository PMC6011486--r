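# File conventions: 4D velocity fields travel as three NIfTI volumes
# (vx/vy/vz) plus a JSON sidecar with the acquisition metadata; CINE series
# as a single-slice 4D NIfTI plus sidecar; masks as 0/1 NIfTI; cohort
# tables as CSV; centerlines, planes and results as JSON.

#' Write a velocity field as NIfTI volumes plus a JSON sidecar
#'
#' Creates `<prefix>_vx.nii.gz`, `<prefix>_vy.nii.gz`, `<prefix>_vz.nii.gz`
#' and `<prefix>.json` (fields `venc_m_per_s`, `dt_ms`, `spacing_mm`,
#' `n_phases`, and any extra metadata supplied).
#'
#' @param field A [velocity_field()].
#' @param prefix output path prefix.
#' @param extra named list merged into the sidecar (e.g. the phantom seed).
#' @return The sidecar path, invisibly.
#' @export
write_velocity_field <- function(field, prefix, extra = list()) {
  stopifnot(inherits(field, "velocity_field"))
  pd <- c(field$spacing, field$dt_ms / 1000)
  for (comp in c("vx", "vy", "vz")) {
    img <- RNifti::asNifti(field[[comp]], pixdim = pd)
    RNifti::writeNifti(img, paste0(prefix, "_", comp, ".nii.gz"))
  }
  sidecar <- c(list(venc_m_per_s = field$venc, dt_ms = field$dt_ms,
                    spacing_mm = field$spacing, n_phases = dim(field$vx)[4]),
               extra)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a velocity field written by [write_velocity_field()]
#' @param prefix path prefix used when writing.
#' @return A [velocity_field()].
#' @export
read_velocity_field <- function(prefix) {
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  comp <- lapply(c("vx", "vy", "vz"), function(cn) {
    arr <- RNifti::readNifti(paste0(prefix, "_", cn, ".nii.gz"))
    array(as.numeric(arr), dim(arr))
  })
  velocity_field(comp[[1]], comp[[2]], comp[[3]],
                 spacing = sc$spacing_mm, dt_ms = sc$dt_ms,
                 venc = sc$venc_m_per_s)
}

#' Write / read a lumen mask as a 0/1 NIfTI volume
#' @param mask A [lumen_mask()].
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_lumen_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lumen_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)),
                         pixdim = mask$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lumen_mask
#' @param spacing_mm voxel spacing override; defaults to the NIfTI pixdim.
#' @export
read_lumen_mask <- function(path, spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(spacing_mm)) spacing_mm <- RNifti::pixdim(img)[1:3]
  lumen_mask(array(as.numeric(img) > 0.5, dim(img)), spacing_mm)
}

#' Write a CINE series as a single-slice NIfTI plus sidecar
#' @param cine A [cine_series()].
#' @param prefix output path prefix.
#' @param extra named list merged into the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_cine_series <- function(cine, prefix, extra = list()) {
  stopifnot(inherits(cine, "cine_series"))
  d <- dim(cine$frames)
  arr <- array(cine$frames, c(d[1], d[2], 1, d[3]))   # X x Y x 1 slice x T
  img <- RNifti::asNifti(arr, pixdim = c(cine$spacing_mm, cine$spacing_mm, 1,
                                         cine$dt_ms / 1000))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  sidecar <- c(list(spacing_mm = cine$spacing_mm, dt_ms = cine$dt_ms,
                    n_phases = d[3]), extra)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CINE series written by [write_cine_series()]
#' @param prefix path prefix used when writing.
#' @return A [cine_series()].
#' @export
read_cine_series <- function(prefix) {
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  d <- dim(img)
  cine_series(array(as.numeric(img), c(d[1], d[2], d[4])),
              spacing_mm = sc$spacing_mm, dt_ms = sc$dt_ms)
}

#' Write / read a cohort table as CSV
#'
#' Column schema: `id`, `age` (years), `sex` (female/male), `male` (0/1),
#' `pwv` (m/s, plus optional per-method columns `pwv_ttf`, `pwv_half_peak`,
#' `pwv_xcor`), and any covariates (`systolic_bp`, `dc_aao`, ...).
#'
#' @param cohort a cohort data.frame.
#' @param path CSV path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(tab)) tab$sex <- factor(tab$sex, levels = c("female", "male"))
  if (!"male" %in% names(tab) && "sex" %in% names(tab))
    tab$male <- as.integer(tab$sex == "male")
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Serialize a centerline to JSON
#' @param cl A [centerline()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_centerline_json <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  jsonlite::write_json(list(points = cl$points, s_mm = cl$s,
                            tangents = cl$tangents),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_centerline_json
#' @export
read_centerline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centerline(obj$points, tangents = obj$tangents)
}

#' Export flow waveforms as a tidy CSV
#' @param waveforms list of flow waveforms.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(waveforms, path) {
  tab <- do.call(rbind, lapply(waveforms, function(w)
    data.frame(plane_id = w$plane_id, s_mm = w$s_mm, t_s = w$t_s,
               q_ml_per_s = w$q_ml_s)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export PWV estimates as JSON
#' @param estimates named list of [fit_pwv()] results (as from
#'   [estimate_pwv()]).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_pwv_json <- function(estimates, path) {
  out <- lapply(estimates, function(e)
    list(method = e$method, pwv_m_per_s = e$pwv,
         slope_s_per_mm = e$slope_s_per_mm, intercept_s = e$intercept_s,
         r_squared = e$r_squared, n_planes = e$n_planes, valid = e$valid))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
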