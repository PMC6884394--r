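# Phantom atlas: disjoint compact regions on a 3D voxel grid standing in for
# anatomical ROIs (signal and control prefrontal regions, visual and motor
# cortex, white matter, striatum) at 3 mm isotropic resolution.

PHANTOM_REGIONS <- c("vlpfc_signal", "dlpfc_null", "visual", "motor",
                     "white_matter", "striatum")

#' Construct a phantom atlas
#'
#' Carves up to 8 compact, quasi-spherical regions into disjoint octants of
#' the grid. Each region consists of the `region_sizes[i]` voxels closest to a
#' jittered octant center, so regions are disjoint by construction and
#' approximately ball-shaped.
#'
#' @param shape Grid dimensions (default 24 x 24 x 24).
#' @param region_sizes Named integer vector of voxel counts per region
#'   (default: 200 voxels for each of the six standard regions).
#' @param voxel_size_mm Isotropic voxel size (metadata; default 3).
#' @param seed Optional integer seed (jitters region centers).
#' @return A `phantom_atlas`: list with `labels` (integer 3D array, 0 =
#'   background), `regions` (name -> label id), `shape`, `voxel_size_mm`.
#' @export
make_phantom_atlas <- function(shape = c(24L, 24L, 24L),
                               region_sizes = stats::setNames(
                                 rep(200L, 6L), PHANTOM_REGIONS),
                               voxel_size_mm = 3, seed = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop_input("`shape` must be 3D")
  n_regions <- length(region_sizes)
  if (is.null(names(region_sizes)) || anyDuplicated(names(region_sizes)))
    stop_input("`region_sizes` must have unique names")
  if (n_regions > 8L) stop_input("at most 8 regions can be packed")
  half <- shape %/% 2L
  octant_vol <- prod(half)
  if (any(region_sizes > octant_vol))
    stop_input("infeasible packing: a region exceeds its octant (",
               octant_vol, " voxels)")
  with_seed(seed, {
    labels <- array(0L, shape)
    corners <- expand.grid(x = c(0L, half[1]), y = c(0L, half[2]),
                           z = c(0L, half[3]))
    for (i in seq_len(n_regions)) {
      lo <- as.integer(corners[i, ])
      hi <- pmin(lo + half, shape)
      ctr <- (lo + hi + 1) / 2 + stats::runif(3, -0.5, 0.5)
      g <- expand.grid(x = (lo[1] + 1L):hi[1], y = (lo[2] + 1L):hi[2],
                       z = (lo[3] + 1L):hi[3])
      d <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
      pick <- g[order(d), ][seq_len(region_sizes[i]), ]
      labels[cbind(pick$x, pick$y, pick$z)] <- i
    }
    structure(list(labels = labels,
                   regions = stats::setNames(seq_len(n_regions),
                                             names(region_sizes)),
                   shape = shape, voxel_size_mm = voxel_size_mm),
              class = "phantom_atlas")
  })
}

#' Logical mask of one atlas region
#'
#' @param atlas A `phantom_atlas`.
#' @param region Region name (or `"brain"` for all labeled voxels).
#' @export
atlas_mask <- function(atlas, region) {
  if (identical(region, "brain")) return(atlas$labels > 0L)
  if (!region %in% names(atlas$regions))
    stop_input("unknown region: ", region)
  atlas$labels == atlas$regions[[region]]
}

#' Named list of all region masks
#' @param atlas A `phantom_atlas`.
#' @export
atlas_masks <- function(atlas) {
  stats::setNames(lapply(names(atlas$regions), function(r) atlas_mask(atlas, r)),
                  names(atlas$regions))
}

#' Write / read a phantom atlas as an integer-labeled NIfTI volume
#'
#' Region names are stored alongside in a small JSON sidecar so the label
#' mapping round-trips exactly.
#' @param atlas A `phantom_atlas`.
#' @param path Output path (`.nii.gz`).
#' @export
write_atlas <- function(atlas, path) {
  img <- RNifti::asNifti(atlas$labels,
                         pixdim = rep(atlas$voxel_size_mm, 3))
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(list(regions = as.list(atlas$regions),
                            voxel_size_mm = atlas$voxel_size_mm),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  labels <- array(as.integer(img), dim = dim(img))
  structure(list(labels = labels,
                 regions = unlist(side$regions),
                 shape = dim(labels),
                 voxel_size_mm = side$voxel_size_mm),
            class = "phantom_atlas")
}
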