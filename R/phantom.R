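## Digital phantom: ground-truth tissue maps and forward simulation of every
## raw input the pipeline consumes (SPGR triplet, multi-shell DWI, FLAIR-like
## volume, region masks) plus the subject-level cohort table.

#' Tissue preset for the digital phantom
#'
#' Voxel-level ground-truth parameters for one tissue class.
#'
#' @param delta_app MT saturation per excitation (dimensionless, typically
#'   0.01-0.05 in brain at 3 T).
#' @param viso Isotropic (free-water) signal fraction in \[0, 1\].
#' @param vic Intra-neurite signal fraction in \[0, 1\].
#' @param odi Orientation dispersion index in (0, 1\].
#' @param direction Length-3 fibre direction (normalized internally).
#' @param r1 Longitudinal relaxation rate, 1/s.
#' @param amplitude Equilibrium signal amplitude (proton density x gain).
#' @return A list of class `tissue_preset`.
#' @export
tissue_preset <- function(delta_app, viso, vic, odi,
                          direction = c(0, 0, 1), r1 = 1.0, amplitude = 1000) {
  for (v in list(viso = viso, vic = vic, odi = odi)) {
    if (v < 0 || v > 1) stop("fractions and ODI must lie in [0, 1]")
  }
  if (odi <= 0) stop("odi must be positive (use 1 for fully dispersed)")
  if (delta_app < 0 || delta_app >= 1) stop("delta_app must be in [0, 1)")
  if (r1 <= 0 || amplitude < 0) stop("r1 must be positive, amplitude non-negative")
  structure(list(delta_app = delta_app, viso = viso, vic = vic, odi = odi,
                 direction = direction / sqrt(sum(direction^2)),
                 r1 = r1, amplitude = amplitude),
            class = "tissue_preset")
}

#' Phantom specification
#'
#' Defines the digital head phantom: grid, voxel size, the three tissue
#' presets (non-WM brain background, normal-appearing white matter, lesion),
#' spherical lesion geometry, the MTsat-to-MVF scaling constant used as
#' ground truth, and the acquisition noise level.
#'
#' The default presets encode a demyelinating-lesion scenario: lesion tissue
#' with MVF 0.3375, viso 0.15, vic 0.3552 (AVF 0.20, aggregate g-ratio
#' 0.610) inside normal-appearing white matter with MVF 0.415, viso 0.05,
#' vic 0.36 (AVF 0.20, g-ratio 0.570) -- i.e. thinner myelin at preserved
#' axonal volume inside lesions.
#'
#' @param grid_shape Three positive integers; default 32 x 32 x 16.
#' @param voxel_size_mm Three positive voxel edge lengths, mm.
#' @param background,nawm,lesion [tissue_preset]s for the three classes.
#' @param lesions List of lesions, each `list(centre = c(i, j, k), radius = r)`
#'   in voxel units.
#' @param k_true Ground-truth myelin volume fraction per unit MTsat
#'   (MVF = k * delta_app).
#' @param snr Signal-to-noise ratio of the simulated magnitude images,
#'   defined against the NAWM PD-weighted signal; `Inf` for noiseless.
#' @param seed Integer seed controlling all phantom randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16),
                         voxel_size_mm = c(2, 2, 2),
                         background = tissue_preset(0.015, 0.50, 0.25, 0.80,
                                                    r1 = 0.7),
                         nawm = tissue_preset(0.0415, 0.05, 0.3419 / 0.95, 0.20,
                                              r1 = 1.0),
                         lesion = tissue_preset(0.03375, 0.15, 0.3552, 0.30,
                                                r1 = 0.85),
                         lesions = list(
                           list(centre = c(11, 16, 8), radius = 3),
                           list(centre = c(21, 16, 8), radius = 3)
                         ),
                         k_true = 10,
                         snr = 40,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("grid_shape must be three integers >= 4")
  }
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  for (p in list(background, nawm, lesion)) {
    if (!inherits(p, "tissue_preset")) stop("tissue presets must be tissue_preset objects")
  }
  for (i in seq_along(lesions)) {
    le <- lesions[[i]]
    if (is.null(le$centre) || length(le$centre) != 3L || is.null(le$radius) ||
        le$radius <= 0) {
      stop("lesion ", i, " must have a length-3 centre and a positive radius")
    }
  }
  if (k_true <= 0) stop("k_true must be positive")
  for (p in list(nawm, lesion, background)) {
    if (k_true * p$delta_app >= 1) {
      stop("implied true MVF = k_true * delta_app must be < 1 for every preset")
    }
  }
  if (snr <= 0) stop("snr must be positive (Inf for noiseless)")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 background = background, nawm = nawm, lesion = lesion,
                 lesions = lesions, k_true = k_true, snr = snr,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Squared normalized ellipsoid coordinate of every voxel; <= 1 is inside.
ellipsoid_dist2 <- function(shape, semi_axes) {
  centre <- (shape + 1) / 2
  ax <- array(0, dim = shape)
  for (d in 1:3) {
    coord <- (slice.index(ax, d) - centre[d]) / semi_axes[d]
    ax <- ax + coord^2
  }
  ax
}

#' Build ground-truth maps and region masks from a phantom specification
#'
#' The intracranial volume (ICV) is an ellipsoid filling 90% of each grid
#' half-extent, white matter (WM) a concentric ellipsoid at 64%, lesions are
#' voxelized spheres (a voxel belongs to a lesion when its centre lies within
#' the radius), and NAWM is WM minus the lesion union. Every lesion must lie
#' entirely inside WM.
#'
#' @param spec A [phantom_spec].
#' @return `list(gt = ground-truth maps, masks = region masks)`. The ground
#'   truth holds voxelwise `delta_app`, `viso`, `vic`, `odi`, `r1_true`,
#'   `a_true` arrays, a 4-D `direction` array (last dim = xyz) and the scalar
#'   `k_true`; masks are logical `icv`, `wm`, `wml`, `nawm` arrays.
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  icv <- ellipsoid_dist2(shape, 0.45 * shape) <= 1
  wm <- ellipsoid_dist2(shape, 0.32 * shape) <= 1
  wml <- array(FALSE, dim = shape)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  for (i in seq_along(spec$lesions)) {
    le <- spec$lesions[[i]]
    d2 <- (idx[, 1] - le$centre[1])^2 + (idx[, 2] - le$centre[2])^2 +
      (idx[, 3] - le$centre[3])^2
    inside <- d2 <= le$radius^2
    if (any(inside & !wm)) {
      stop("lesion ", i, " extends outside the white-matter region")
    }
    wml[inside] <- TRUE
  }
  nawm <- wm & !wml
  masks <- structure(list(icv = icv, wm = wm, wml = wml, nawm = nawm),
                     class = "region_masks")

  fill <- function(field) {
    out <- array(0, dim = shape)
    out[icv] <- spec$background[[field]]
    out[nawm] <- spec$nawm[[field]]
    out[wml] <- spec$lesion[[field]]
    out
  }
  direction <- array(0, dim = c(shape, 3))
  for (d in 1:3) {
    sl <- array(0, dim = shape)
    sl[icv] <- spec$background$direction[d]
    sl[nawm] <- spec$nawm$direction[d]
    sl[wml] <- spec$lesion$direction[d]
    direction[, , , d] <- sl
  }
  gt <- structure(list(
    delta_app = fill("delta_app"), viso = fill("viso"), vic = fill("vic"),
    odi = fill("odi"), direction = direction,
    r1_true = fill("r1"), a_true = fill("amplitude"),
    k_true = spec$k_true,
    voxel_size_mm = spec$voxel_size_mm
  ), class = "ground_truth_maps")
  list(gt = gt, masks = masks)
}

## Full SPGR steady-state signal. The MT pulse saturates longitudinal
## magnetization by (1 - delta) each TR inside the steady-state recursion:
##   S = A sin(a) (1 - E) / (1 - cos(a) (1 - delta) E),  E = exp(-R1 TR).
spgr_signal <- function(A, r1, flip_rad, tr_s, delta = 0) {
  E <- exp(-r1 * tr_s)
  A * sin(flip_rad) * (1 - E) / (1 - cos(flip_rad) * (1 - delta) * E)
}

#' Forward-simulate the SPGR triplet
#'
#' Noiseless PD-weighted, T1-weighted and MT-weighted spoiled gradient echo
#' volumes from ground-truth amplitude, R1 and MTsat maps, using the full
#' steady-state expression. The MT-weighted volume additionally carries the
#' per-TR saturation `(1 - delta_app)` of longitudinal magnetization.
#'
#' @param gt Ground-truth maps from [make_ground_truth()].
#' @param protocol An [acquisition_protocol].
#' @return Named list of three [signal_volume]s: `pdw`, `t1w`, `mtw`.
#' @export
simulate_spgr <- function(gt, protocol) {
  stopifnot(inherits(gt, "ground_truth_maps"),
            inherits(protocol, "acquisition_protocol"))
  vols <- list()
  for (nm in c("pdw", "t1w", "mtw")) {
    s <- protocol$spgr[[nm]]
    if (s$flip_rad <= 0) stop("flip angle for ", nm, " must be positive")
    delta <- if (nm == "mtw") gt$delta_app else 0
    sig <- spgr_signal(gt$a_true, gt$r1_true, s$flip_rad, s$tr_s, delta)
    vols[[nm]] <- signal_volume(sig, voxel_size_mm = gt$voxel_size_mm)
  }
  vols
}

#' Forward-simulate the multi-shell diffusion acquisition
#'
#' Applies the shared NODDI kernel (see [predict_noddi_signal()]) voxelwise:
#' `S = S0 * [(1 - viso)(vic A_ic + (1 - vic) A_ec) + viso exp(-b d_iso)]`,
#' with `S0 = a_true`. Voxels are grouped by unique tissue parameters so the
#' piecewise-constant phantom simulates in a handful of kernel evaluations.
#'
#' @inheritParams simulate_spgr
#' @return A 4-D [signal_volume]; fourth dimension indexes the gradient table.
#' @export
simulate_dwi <- function(gt, protocol) {
  stopifnot(inherits(gt, "ground_truth_maps"),
            inherits(protocol, "acquisition_protocol"))
  if (any(protocol$bvals < 0)) stop("negative b-value in gradient table")
  shape <- dim(gt$a_true)
  nvol <- length(protocol$bvals)
  nvox <- prod(shape)
  dirmat <- matrix(gt$direction, nrow = nvox, ncol = 3)
  key <- paste(gt$viso, gt$vic, gt$odi, dirmat[, 1], dirmat[, 2], dirmat[, 3],
               sep = "|")
  key[gt$a_true <= 0] <- NA   # no signal to simulate
  out <- matrix(0, nrow = nvox, ncol = nvol)
  for (k in unique(key[!is.na(key)])) {
    vox <- which(!is.na(key) & key == k)
    v <- vox[1]
    att <- predict_noddi_signal(gt$viso[v], gt$vic[v], gt$odi[v],
                                dirmat[v, ], protocol)
    out[vox, ] <- outer(gt$a_true[vox], att)
  }
  signal_volume(array(out, dim = c(shape, nvol)),
                voxel_size_mm = gt$voxel_size_mm)
}

## Run expr with a temporary RNG state seeded by `seed`, restoring the
## caller's state afterwards.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Add Rician noise to a magnitude volume
#'
#' Each voxel value S is replaced by `sqrt((S + n1)^2 + n2^2)` with `n1`,
#' `n2` independent zero-mean Gaussians of standard deviation
#' `reference_signal / snr` -- the magnitude-MRI noise model. The output is
#' reproducible under a fixed seed and leaves the caller's RNG state intact.
#'
#' @param vol A [signal_volume].
#' @param snr Positive signal-to-noise ratio; `Inf` returns the input
#'   unchanged.
#' @param reference_signal Signal level against which `snr` is defined
#'   (conventionally the NAWM PD-weighted signal).
#' @param seed Integer seed.
#' @return A [signal_volume] of the same shape.
#' @export
add_rician_noise <- function(vol, snr, reference_signal, seed = 1L) {
  stopifnot(inherits(vol, "signal_volume"))
  if (snr <= 0) stop("snr must be positive")
  if (!is.finite(snr)) return(vol)
  if (reference_signal <= 0) stop("reference_signal must be positive")
  sigma <- reference_signal / snr
  n <- length(vol$data)
  noisy <- with_local_seed(seed, {
    sqrt((vol$data + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  })
  signal_volume(array(noisy, dim = dim(vol$data)),
                voxel_size_mm = vol$voxel_size_mm, affine = vol$affine)
}

#' Simulate a FLAIR-like volume
#'
#' A stylized T2-FLAIR: Gaussian intensities with tissue-specific means,
#' lesions hyperintense relative to white matter by `contrast` noise
#' standard deviations. Supports testing of the intensity-threshold lesion
#' segmenter; it makes no claim to sequence realism.
#'
#' @param gt Ground-truth maps (used only for the grid).
#' @param masks Region masks from [make_ground_truth()].
#' @param contrast Lesion minus WM mean intensity, in units of `noise_sd`.
#' @param wm_mean,gm_mean Mean intensities of white matter and of
#'   non-WM intracranial tissue.
#' @param noise_sd Intensity standard deviation, shared by all tissues.
#' @param seed Integer seed.
#' @return A 3-D [signal_volume].
#' @export
simulate_flair <- function(gt, masks, contrast = 5, wm_mean = 100,
                           gm_mean = 80, noise_sd = 10, seed = 1L) {
  shape <- dim(masks$icv)
  mean_img <- array(0, dim = shape)
  mean_img[masks$icv] <- gm_mean
  mean_img[masks$wm] <- wm_mean
  mean_img[masks$wml] <- wm_mean + contrast * noise_sd
  img <- with_local_seed(seed, {
    mean_img + rnorm(length(mean_img), sd = noise_sd) * (mean_img > 0)
  })
  img[img < 0] <- 0
  signal_volume(img, voxel_size_mm = gt$voxel_size_mm)
}

#' Simulate the complete imaging study for one phantom
#'
#' Convenience wrapper: builds the ground truth and masks, forward-simulates
#' the SPGR triplet, the multi-shell DWI and the FLAIR-like volume, and adds
#' Rician noise at `spec$snr` referenced to the median NAWM PD-weighted
#' signal. Sub-seeds for the per-volume noise draws are derived
#' deterministically from `spec$seed`.
#'
#' @param spec A [phantom_spec].
#' @param protocol An [acquisition_protocol]; default [default_protocol()].
#' @return List with `gt`, `masks`, `protocol`, `reference_signal` and
#'   `volumes` (named list: `pdw`, `t1w`, `mtw`, `dwi`, `flair`).
#' @export
simulate_phantom <- function(spec, protocol = default_protocol()) {
  truth <- make_ground_truth(spec)
  spgr <- simulate_spgr(truth$gt, protocol)
  dwi <- simulate_dwi(truth$gt, protocol)
  flair <- simulate_flair(truth$gt, truth$masks, seed = spec$seed + 4L)
  ref <- stats::median(spgr$pdw$data[truth$masks$nawm])
  vols <- list(
    pdw = add_rician_noise(spgr$pdw, spec$snr, ref, seed = spec$seed),
    t1w = add_rician_noise(spgr$t1w, spec$snr, ref, seed = spec$seed + 1L),
    mtw = add_rician_noise(spgr$mtw, spec$snr, ref, seed = spec$seed + 2L),
    dwi = add_rician_noise(dwi, spec$snr,
                           stats::median(truth$gt$a_true[truth$masks$nawm]),
                           seed = spec$seed + 3L),
    flair = flair
  )
  list(gt = truth$gt, masks = truth$masks, protocol = protocol,
       reference_signal = ref, volumes = vols)
}
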