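# Image-volume plumbing: b0 normalization of 4D acquisitions, masked
# voxelwise fitting, and NIfTI parametric-map output.

#' Normalize a 4D diffusion acquisition by per-TE b = 0 volumes
#'
#' Divides each diffusion-weighted volume voxelwise by the b = 0 volume
#' acquired at the same echo time, then appends one normalized b = 0 volume
#' (identically 1) per echo time so each voxel vector has the protocol's
#' full measurement count. Voxels where any required b0 is zero or non-finite
#' are removed from the mask and counted.
#'
#' @param dwi 4D array (x, y, z, n_dw) of diffusion-weighted volumes, in the
#'   order of the protocol's non-b0 rows.
#' @param b0 4D array (x, y, z, n_te) of b = 0 volumes, one per unique echo
#'   time in the order the echo times first appear among the protocol's
#'   non-b0 rows.
#' @param protocol A `pgse_protocol` whose b = 0 rows come after the
#'   diffusion-weighted rows.
#' @param mask Optional 3D logical array; defaults to all voxels.
#' @return List of class `normalized_volume`: `data` (x, y, z, N_d array),
#'   `mask`, `n_masked_out`, `protocol`.
#' @export
normalize_volume <- function(dwi, b0, protocol, mask = NULL) {
  stopifnot(inherits(protocol, "pgse_protocol"))
  dw_rows <- which(!protocol$is_b0)
  b0_rows <- which(protocol$is_b0)
  tes <- unique(protocol$te[dw_rows])
  if (length(dim(dwi)) != 4 || dim(dwi)[4] != length(dw_rows)) {
    abort(sprintf("dwi must be 4D with %d volumes", length(dw_rows)))
  }
  if (length(dim(b0)) != 4 || dim(b0)[4] != length(tes)) {
    abort(sprintf("b0 must be 4D with %d volumes (one per echo time)",
                  length(tes)))
  }
  missing_te <- setdiff(protocol$te[dw_rows], protocol$te[b0_rows])
  if (length(missing_te) > 0) {
    abort(sprintf("no b = 0 measurement for TE = %s s",
                  paste(signif(missing_te, 4), collapse = ", ")))
  }
  geom <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, geom)
  te_index <- match(protocol$te[dw_rows], tes)
  bad <- array(FALSE, geom)
  for (k in seq_along(tes)) {
    v <- b0[, , , k, drop = FALSE]
    bad <- bad | !is.finite(v[, , , 1]) | abs(v[, , , 1]) < 1e-12
  }
  n_masked <- sum(bad & mask)
  mask <- mask & !bad
  out <- array(NA_real_, c(geom, nrow(protocol)))
  for (j in seq_along(dw_rows)) {
    out[, , , dw_rows[j]] <- dwi[, , , j] / b0[, , , te_index[j]]
  }
  for (j in seq_along(b0_rows)) out[, , , b0_rows[j]] <- 1
  structure(list(data = out, mask = mask, n_masked_out = n_masked,
                 protocol = protocol),
            class = "normalized_volume")
}

#' Fit every masked voxel of a normalized volume
#'
#' @param volume A `normalized_volume`.
#' @param engine `"amico"` or `"nlls"`.
#' @param dict Dictionary for the amico engine (built from the volume's
#'   protocol when omitted).
#' @param ... Passed on to [fit_amico()] or [fit_nlls()].
#' @return List of class `verdict_maps`: 3D arrays `f_ic`, `f_ees`,
#'   `f_vasc`, `radius_um`, `d_ees`, `f_obj` (NA outside the mask and for
#'   undefined radii), plus the per-voxel `fit`.
#' @export
fit_volume <- function(volume, engine = c("amico", "nlls"), dict = NULL, ...) {
  stopifnot(inherits(volume, "normalized_volume"))
  engine <- match.arg(engine)
  geom <- dim(volume$data)[1:3]
  idx <- which(volume$mask)
  flat <- matrix(volume$data, prod(geom), dim(volume$data)[4])
  signals <- flat[idx, , drop = FALSE]
  fit <- if (engine == "amico") {
    if (is.null(dict)) dict <- verdict_dictionary(volume$protocol)
    fit_amico(signals, dict, ...)
  } else {
    fit_nlls(signals, volume$protocol, ...)
  }
  p <- fit$params
  maps <- list()
  fill <- function(vals) {
    m <- array(NA_real_, geom)
    m[idx] <- vals
    m
  }
  maps$f_ic <- fill(p$f_ic)
  maps$f_ees <- fill(p$f_ees)
  maps$f_vasc <- fill(p$f_vasc)
  maps$radius_um <- fill(p$radius * 1e6)
  maps$d_ees <- fill(p$d_ees)
  maps$f_obj <- fill(p$f_obj)
  # conspicuity-enhancing ratio map, defined where d_EES > 0
  maps$f_ic_over_d_ees <- fill(ifelse(p$d_ees > 0, p$f_ic / p$d_ees, NA_real_))
  structure(list(maps = maps, fit = fit, mask = volume$mask,
                 protocol = volume$protocol),
            class = "verdict_maps")
}

#' Write parametric maps as NIfTI files
#'
#' One scalar NIfTI volume per parameter (`f_ic.nii.gz`, ...), with geometry
#' and orientation copied from a reference image when given. The radius map
#' is in um; undefined radii stay `NA`.
#'
#' @param maps A `verdict_maps` object.
#' @param dir Output directory.
#' @param reference Optional reference NIfTI image (path or `niftiImage`)
#'   whose geometry metadata is copied; its 3D dimensions must match.
#' @return Tibble of written files, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, reference = NULL) {
  stopifnot(inherits(maps, "verdict_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- NULL
  if (!is.null(reference)) {
    ref <- if (is.character(reference)) RNifti::readNifti(reference) else reference
    if (!all(dim(ref)[1:3] == dim(maps$maps$f_ic))) {
      abort("reference geometry does not match the fitted volume")
    }
  }
  files <- character(0)
  for (nm in names(maps$maps)) {
    img <- maps$maps[[nm]]
    nii <- if (is.null(ref)) RNifti::asNifti(img)
           else RNifti::asNifti(img, reference = ref)
    path <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(nii, path)
    files <- c(files, path)
  }
  invisible(tibble(parameter = names(maps$maps), path = files))
}
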