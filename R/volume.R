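#' Reconstruction grid specification
#'
#' Defines an isotropic voxel grid centred (by default) on the scanner
#' isocenter. Voxel centres lie at \code{origin + index * voxel} (0-based
#' indices, world units mm, array indexed x-fastest).
#'
#' @param n integer vector of length 1 or 3: grid size (voxels).
#' @param voxel isotropic voxel size in mm.
#' @param center world coordinates (mm) of the grid centre.
#' @return an object of class \code{recon_grid}.
#' @export
recon_grid <- function(n, voxel, center = c(0, 0, 0)) {
  if (length(n) == 1) n <- rep(n, 3)
  stopifnot(length(n) == 3, all(n >= 1), voxel > 0, length(center) == 3)
  n <- as.integer(n)
  origin <- center - (n - 1) / 2 * voxel
  structure(list(n = n, voxel = voxel, origin = origin, center = center),
            class = "recon_grid")
}

#' Construct a volume object
#'
#' A \code{ct_volume} is a 3D scalar grid of linear attenuation values
#' (1/mm) with voxel size, world origin and a provenance record
#' (\code{Std}, \code{PC(bin)}, \code{MoCo}, \code{TBAF(...)} and the
#' parameters that produced it).
#'
#' @param data 3D numeric array (x, y, z).
#' @param voxel voxel size mm.
#' @param origin world position (mm) of voxel (1,1,1) centre.
#' @param provenance named list describing how the volume was produced.
#' @export
new_volume <- function(data, voxel, origin, provenance = list(tag = "raw")) {
  stopifnot(is.array(data), length(dim(data)) == 3, voxel > 0)
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  structure(list(data = data, voxel = voxel, origin = as.numeric(origin),
                 provenance = provenance),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %dx%dx%d @ %.4g mm, tag=%s\n", d[1], d[2], d[3],
              x$voxel, if (is.null(x$provenance$tag)) "?" else x$provenance$tag))
  invisible(x)
}

#' @rdname new_volume
#' @param grid a \code{recon_grid}.
#' @export
empty_volume <- function(grid, provenance = list(tag = "empty")) {
  new_volume(array(0, dim = grid$n), grid$voxel, grid$origin, provenance)
}

#' Hounsfield unit conversion
#'
#' HU = 1000 (mu - mu_water) / mu_water; the inverse is exact.
#'
#' @param mu attenuation values (1/mm); @param hu Hounsfield units.
#' @param mu_water attenuation of water at the effective energy (1/mm).
#' @export
mu_to_hu <- function(mu, mu_water = 0.02) 1000 * (mu - mu_water) / mu_water

#' @rdname mu_to_hu
#' @export
hu_to_mu <- function(hu, mu_water = 0.02) mu_water * (1 + hu / 1000)

#' Convert a volume to HU
#' @param vol a \code{ct_volume} holding mu values.
#' @inheritParams mu_to_hu
#' @export
volume_hu <- function(vol, mu_water = 0.02) mu_to_hu(vol$data, mu_water)

#' World coordinates of voxel centres along each axis
#' @param vol a \code{ct_volume}.
#' @export
volume_axes <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$voxel)
}

#' Write / read volumes as NIfTI
#'
#' Volumes are stored in NIfTI-1 with the voxel spacing recorded in pixdim
#' and the world origin in the sform; provenance is written to a JSON
#' sidecar next to the image.
#'
#' @param vol a \code{ct_volume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, rep(vol$voxel, 3))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(voxel_mm = vol$voxel, origin_mm = vol$origin,
                            provenance = vol$provenance),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  voxel <- RNifti::pixdim(img)[1]
  origin <- NULL
  prov <- list(tag = "loaded")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    voxel <- meta$voxel_mm
    origin <- meta$origin_mm
    prov <- as.list(meta$provenance)
  }
  d <- dim(img)
  if (is.null(origin)) origin <- -(d - 1) / 2 * voxel
  new_volume(array(as.numeric(img), dim = d), voxel, origin, prov)
}
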