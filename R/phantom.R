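#' Geometric insert for a voxelized phantom
#'
#' @param type `"ellipsoid"`, `"cylinder"` (elliptical cross-section, axis
#'   along z) or `"sphere"`.
#' @param center World mm center (length 3).
#' @param semiaxes For ellipsoids: the three semi-axes, mm. For cylinders: the
#'   two in-plane semi-axes, mm.
#' @param radius Sphere radius, mm.
#' @param half_length Cylinder half-length along z, mm.
#' @param mu Linear attenuation coefficient painted inside the insert, 1/mm.
#' @param name Label used in error messages.
#' @return A list describing the insert.
#' @export
phantom_insert <- function(type = c("ellipsoid", "cylinder", "sphere"),
                           center, semiaxes = NULL, radius = NULL,
                           half_length = NULL, mu, name = type) {
  type <- match.arg(type)
  if (mu < 0) stop("attenuation must be >= 0 for insert '", name, "'")
  list(type = type, center = as.numeric(center), semiaxes = semiaxes,
       radius = radius, half_length = half_length, mu = mu, name = name)
}

#' Default digital thorax phantom layout
#'
#' A water-equivalent body ellipse, two low-attenuation lungs, a
#' high-attenuation spine cylinder and a soft-tissue lesion sphere, mimicking
#' a thorax quality-assurance phantom. `scale = 1` gives an adult-thorax-sized
#' body (300 x 200 mm cross-section); the reduced desk scale used by the
#' bundled experiments passes `scale` &lt; 1 so the whole body fits inside a
#' small local reconstruction volume.
#'
#' Attenuation values are nominal 6 MV linear attenuation coefficients:
#' water 0.005/mm, lung 0.0012/mm, bone 0.008/mm, lesion 0.006/mm.
#'
#' @param scale Isotropic scale factor applied to all insert dimensions.
#' @return A list of [phantom_insert()]s (painted in order, later inserts
#'   overwrite earlier ones).
#' @export
default_thorax_spec <- function(scale = 1) {
  s <- scale
  list(
    phantom_insert("ellipsoid", center = c(0, 0, 0),
                   semiaxes = c(150, 100, 130) * s, mu = 0.005,
                   name = "body"),
    phantom_insert("ellipsoid", center = c(-70, -10, 0) * s,
                   semiaxes = c(55, 65, 90) * s, mu = 0.0012,
                   name = "left lung"),
    phantom_insert("ellipsoid", center = c(70, -10, 0) * s,
                   semiaxes = c(55, 65, 90) * s, mu = 0.0012,
                   name = "right lung"),
    phantom_insert("cylinder", center = c(0, 65, 0) * s,
                   semiaxes = c(18, 18) * s, half_length = 130 * s,
                   mu = 0.008, name = "spine"),
    phantom_insert("sphere", center = c(-40, -20, 25) * s,
                   radius = 16 * s, mu = 0.006, name = "lesion")
  )
}

insert_bbox <- function(ins) {
  switch(ins$type,
    ellipsoid = rbind(ins$center - ins$semiaxes, ins$center + ins$semiaxes),
    cylinder = rbind(ins$center - c(ins$semiaxes, ins$half_length),
                     ins$center + c(ins$semiaxes, ins$half_length)),
    sphere = rbind(ins$center - ins$radius, ins$center + ins$radius)
  )
}

#' Build a voxelized thorax-like attenuation phantom
#'
#' Paints each insert of `spec` (in order) onto a zero-attenuation grid; a
#' voxel belongs to an insert when its center lies inside the analytic shape,
#' so the map is piecewise constant and bit-reproducible.
#'
#' @param grid_shape Grid dimensions (length 3).
#' @param voxel_size Voxel size, mm (length 3).
#' @param spec List of [phantom_insert()]s; defaults to the thorax layout.
#' @param origin Grid origin (corner of voxel (0,0,0)); `NULL` centers the
#'   grid on the isocenter.
#' @return A [volume_image()] with modality `"attenuation"`.
#' @export
build_thorax_phantom <- function(grid_shape, voxel_size,
                                 spec = default_thorax_spec(),
                                 origin = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape <= 0)) stop("grid_shape must be positive")
  vol <- volume_image(array(0, dim = grid_shape), voxel_size, origin,
                      modality = "attenuation")
  lo <- vol$origin
  hi <- vol$origin + grid_shape * vol$voxel_size
  xs <- lo[1] + (seq_len(grid_shape[1]) - 0.5) * vol$voxel_size[1]
  ys <- lo[2] + (seq_len(grid_shape[2]) - 0.5) * vol$voxel_size[2]
  zs <- lo[3] + (seq_len(grid_shape[3]) - 0.5) * vol$voxel_size[3]
  for (ins in spec) {
    bb <- insert_bbox(ins)
    if (any(bb[1, ] < lo) || any(bb[2, ] > hi)) {
      stop("insert '", ins$name, "' extends outside the phantom grid")
    }
    mask <- switch(ins$type,
      ellipsoid = {
        a <- ins$semiaxes
        ex <- ((xs - ins$center[1]) / a[1])^2
        ey <- ((ys - ins$center[2]) / a[2])^2
        ez <- ((zs - ins$center[3]) / a[3])^2
        outer(outer(ex, ey, "+"), ez, "+") <= 1
      },
      cylinder = {
        a <- ins$semiaxes
        ex <- ((xs - ins$center[1]) / a[1])^2
        ey <- ((ys - ins$center[2]) / a[2])^2
        inplane <- outer(ex, ey, "+") <= 1
        inz <- abs(zs - ins$center[3]) <= ins$half_length
        outer(inplane, inz, "&")
      },
      sphere = {
        ex <- (xs - ins$center[1])^2
        ey <- (ys - ins$center[2])^2
        ez <- (zs - ins$center[3])^2
        outer(outer(ex, ey, "+"), ez, "+") <= ins$radius^2
      }
    )
    vol$values[mask] <- ins$mu
  }
  vol
}

#' Convert an attenuation map to a planning-CT-like volume
#'
#' Maps linear attenuation to a Hounsfield-like scale,
#' `HU = 1000 * (mu / mu_water - 1)`, so the synthetic planning CT carries a
#' different grayscale than the reconstructed MVCT (the registration is
#' intensity-scale agnostic).
#'
#' @param phantom A [volume_image()] of attenuation values.
#' @param mu_water Water attenuation used for the conversion, 1/mm.
#' @return A [volume_image()] with modality `"planning-CT"`.
#' @export
attenuation_to_ct <- function(phantom, mu_water = 0.005) {
  volume_image(1000 * (phantom$values / mu_water - 1), phantom$voxel_size,
               phantom$origin, modality = "planning-CT")
}
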