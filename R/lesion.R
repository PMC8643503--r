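## Lesion masking: robust intensity-threshold segmentation of hyperintense
## lesions on a FLAIR-like volume, NAWM derivation with a partial-volume
## exclusion ring, and ICV-corrected lesion volume.

## Offsets of the 26-neighbourhood (or 6 for face connectivity).
neighbour_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26L) stop("connectivity must be 6 or 26")
  g
}

## Label connected components of a 3-D logical array; returns an integer
## array (0 = background) and component sizes.
label_components <- function(mask, connectivity = 26L) {
  shape <- dim(mask)
  off <- neighbour_offsets(connectivity)
  labels <- array(0L, shape)
  nxt <- 0L
  sizes <- integer(0)
  todo <- which(mask)
  for (s in seq_along(todo)) {
    start <- todo[s]
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      ijk <- arrayInd(cur, shape)
      nb <- sweep(off, 2, as.integer(ijk), "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- nb[, 1] + shape[1] * (nb[, 2] - 1L) + shape[1] * shape[2] * (nb[, 3] - 1L)
      lin <- lin[mask[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
    sizes[nxt] <- size
  }
  list(labels = labels, sizes = sizes)
}

## Binary dilation of a 3-D mask by `radius` voxels (Chebyshev ball, i.e.
## `radius` iterations of the 26-neighbourhood).
dilate_mask <- function(mask, radius = 1L) {
  if (radius <= 0) return(mask)
  shape <- dim(mask)
  out <- mask
  off <- neighbour_offsets(26L)
  for (r in seq_len(radius)) {
    cur <- which(out)
    if (!length(cur)) break
    ijk <- arrayInd(cur, shape)
    grown <- out
    for (o in seq_len(nrow(off))) {
      nb <- sweep(ijk, 2, off[o, ], "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[keep, , drop = FALSE]
      grown[nb[, 1] + shape[1] * (nb[, 2] - 1L) +
              shape[1] * shape[2] * (nb[, 3] - 1L)] <- TRUE
    }
    out <- grown
  }
  out
}

#' Segment hyperintense lesions by robust intensity thresholding
#'
#' Voxels whose intensity exceeds `median + z_threshold * 1.4826 * MAD` of
#' the white-matter intensities are labelled lesion; robust statistics are
#' used because lesion voxels contaminate moment-based estimates. Connected
#' components smaller than `min_size` voxels (26-connectivity by default)
#' are then removed, standing in for the manual editing step of clinical
#' pipelines.
#'
#' @param flair A FLAIR-like [signal_volume].
#' @param wm Logical white-matter mask (lesions included).
#' @param z_threshold Threshold in robust-SD units above the WM centre.
#' @param min_size Minimum connected-component size in voxels.
#' @param connectivity 6 or 26.
#' @return Logical lesion (WML) mask.
#' @export
segment_lesions <- function(flair, wm, z_threshold = 3, min_size = 3L,
                            connectivity = 26L) {
  wm <- as_mask(wm, flair)
  if (!any(wm)) stop("white-matter mask is empty")
  vals <- flair$data[wm]
  centre <- stats::median(vals)
  spread <- stats::mad(vals)   # median/MAD, scaled to SD units
  if (spread <= 0) stop("degenerate WM intensity distribution (zero spread)")
  thr <- centre + z_threshold * spread
  wml <- wm & flair$data > thr
  if (all(wml[wm])) stop("degenerate contrast: all WM voxels above threshold")
  if (any(wml) && min_size > 1L) {
    lab <- label_components(wml, connectivity)
    keep <- which(lab$sizes >= min_size)
    wml <- array(lab$labels %in% keep, dim = dim(wml))
  }
  wml
}

#' Derive the normal-appearing white-matter mask
#'
#' NAWM = WM minus the lesion mask dilated by `exclusion_dilation` voxels.
#' The default 1-voxel ring guards regional NAWM statistics against
#' partial-volume lesion rims.
#'
#' @param wm,wml Logical masks on a common grid.
#' @param exclusion_dilation Dilation radius in voxels (0 = exact set
#'   difference).
#' @return Logical NAWM mask.
#' @export
derive_nawm <- function(wm, wml, exclusion_dilation = 1L) {
  if (!identical(dim(wm), dim(wml))) stop("wm and wml grids differ")
  if (any(wml & !wm)) stop("wml mask must be a subset of the wm mask")
  nawm <- wm & !dilate_mask(wml, exclusion_dilation)
  if (!any(nawm)) stop("NAWM mask is empty after lesion exclusion")
  nawm
}

#' Intracranial-volume-corrected lesion volume
#'
#' Lesion volume as a percentage of intracranial volume,
#' `100 * volume(WML) / volume(ICV)`. Voxel volumes are carried explicitly
#' so the formula remains correct if the two masks ever live on different
#' grids; on a shared grid they cancel into a voxel-count ratio.
#'
#' @param wml,icv Logical masks.
#' @param voxel_size_mm Voxel edge lengths for `wml` (and for `icv` unless
#'   `icv_voxel_size_mm` is given).
#' @param icv_voxel_size_mm Optional separate ICV voxel size.
#' @return Percentage in \[0, 100\].
#' @export
lesion_volume_pct_icv <- function(wml, icv, voxel_size_mm = c(2, 2, 2),
                                  icv_voxel_size_mm = voxel_size_mm) {
  if (!any(icv)) stop("ICV mask is empty")
  100 * (sum(wml) * prod(voxel_size_mm)) / (sum(icv) * prod(icv_voxel_size_mm))
}
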