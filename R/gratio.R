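## Aggregate g-ratio pipeline: healthy-control calibration of the
## MTsat-to-MVF scaling, MVF / AVF maps, the aggregate g-ratio map
## g = (1 + MVF/AVF)^(-1/2), and regional summaries with shared histogram
## bins for lesion vs normal-appearing white matter.

#' Calibrate the MTsat-to-MVF scaling constant on control data
#'
#' MVF is modelled as a linear scaling of MTsat, `MVF = k * delta_app`, with
#' `k` calibrated so that pooled control normal-appearing-white-matter
#' voxels hit a physiological anchor: either a target median MVF
#' (`target = list(type = "median_mvf", value =)`) or a target median
#' aggregate g-ratio (`type = "median_g"`, which additionally needs the
#' controls' NODDI fractions). The g-ratio target is solved by a 1-D root
#' find, exploiting that the voxelwise g-ratio -- and hence its median --
#' decreases strictly in `k`.
#'
#' @param delta_maps A single MTsat array or a list of them (one per control
#'   subject).
#' @param masks A logical NAWM mask, or a list matching `delta_maps`.
#' @param target `list(type = "median_mvf" | "median_g", value =)`; default
#'   anchors the control-NAWM median g-ratio at 0.70.
#' @param viso_maps,vic_maps NODDI fraction maps (or lists), required for
#'   the `"median_g"` target.
#' @return Calibrated scalar `k` (positive).
#' @export
calibrate_k <- function(delta_maps, masks,
                        target = list(type = "median_g", value = 0.70),
                        viso_maps = NULL, vic_maps = NULL) {
  as_list <- function(x) if (is.list(x) && !is.array(x)) x else list(x)
  delta_maps <- as_list(delta_maps)
  masks <- as_list(masks)
  if (length(masks) != length(delta_maps)) {
    stop("need one mask per control delta_app map")
  }
  pool <- function(maps) {
    unlist(lapply(seq_along(maps), function(i) {
      v <- maps[[i]][masks[[i]]]
      v[is.finite(v)]
    }))
  }
  delta <- pool(delta_maps)
  if (length(delta) == 0) stop("pooled control NAWM mask is empty")
  if (!target$type %in% c("median_mvf", "median_g")) {
    stop("target$type must be 'median_mvf' or 'median_g'")
  }
  if (target$type == "median_mvf") {
    if (target$value <= 0 || target$value >= 1) {
      stop("target median MVF must be in (0, 1)")
    }
    return(target$value / stats::median(delta))
  }
  if (is.null(viso_maps) || is.null(vic_maps)) {
    stop("the median_g target requires viso_maps and vic_maps")
  }
  viso <- pool(as_list(viso_maps))
  vic <- pool(as_list(vic_maps))
  if (length(viso) != length(delta) || length(vic) != length(delta)) {
    stop("delta_app, viso and vic must cover the same pooled voxels")
  }
  if (target$value <= 0 || target$value >= 1) {
    stop("target median g must be in (0, 1)")
  }
  med_g <- function(k) {
    mvf <- pmin(pmax(k * delta, 0), 1 - 1e-6)
    avf <- (1 - mvf) * (1 - viso) * vic
    stats::median((1 + mvf / avf)^(-0.5))
  }
  k_hi <- (1 - 1e-6) / max(delta)   # largest k keeping every MVF < 1
  lo <- 1e-8
  if (med_g(lo) < target$value) {
    stop("target median g ", target$value, " unattainable: even k ~ 0 gives ",
         signif(med_g(lo), 4))
  }
  if (med_g(k_hi) > target$value) {
    stop("target median g ", target$value, " unattainable within MVF < 1")
  }
  stats::uniroot(function(k) med_g(k) - target$value, c(lo, k_hi),
                 tol = 1e-12)$root
}

#' Compute the myelin volume fraction map
#'
#' `MVF = k * delta_app`, clipped into `[0, 1 - 1e-6]`. The number of
#' clipped in-mask voxels is reported via an attribute and a warning; under
#' `strict = TRUE` more than 5% clipped voxels is an error.
#'
#' @param delta_app MTsat array.
#' @param k Positive calibration constant.
#' @param mask Optional logical array (defaults to finite voxels).
#' @param strict Escalate the >5%-clipped warning to an error.
#' @return MVF array with attribute `n_clipped`.
#' @export
compute_mvf <- function(delta_app, k, mask = NULL, strict = FALSE) {
  if (k <= 0) stop("k must be positive")
  mask <- as_mask(mask, delta_app) & is.finite(delta_app)
  mvf <- array(NA_real_, dim = dim(delta_app))
  raw <- k * delta_app[mask]
  clipped <- sum(raw < 0 | raw > 1 - 1e-6)
  mvf[mask] <- pmin(pmax(raw, 0), 1 - 1e-6)
  frac <- if (any(mask)) clipped / sum(mask) else 0
  if (frac > 0.05) {
    msg <- sprintf("%.1f%% of in-mask voxels clipped to [0, 1) in MVF", 100 * frac)
    if (strict) stop(msg) else warning(msg)
  }
  attr(mvf, "n_clipped") <- clipped
  mvf
}

#' Compute the axonal volume fraction map
#'
#' `AVF = (1 - MVF) * (1 - viso) * vic`: the axonal water fraction scaled by
#' the non-myelin voxel volume, from the NODDI isotropic and intra-neurite
#' signal fractions.
#'
#' @param mvf MVF array.
#' @param viso,vic NODDI fraction arrays on the same grid.
#' @return AVF array.
#' @export
compute_avf <- function(mvf, viso, vic) {
  check_same_grid(mvf, viso, "MVF and viso maps")
  check_same_grid(mvf, vic, "MVF and vic maps")
  (1 - mvf) * (1 - viso) * vic
}

#' Compute the aggregate g-ratio map
#'
#' `g = (1 + MVF/AVF)^(-1/2)`: the voxel-aggregate ratio of inner axonal to
#' outer fibre radius. Voxels with AVF at or below `avf_floor` (near-CSF
#' voxels where the ratio is unbounded) or non-finite inputs are flagged
#' invalid rather than raised as errors.
#'
#' @param mvf,avf Arrays on a common grid.
#' @param avf_floor Minimum AVF for a voxel to be considered valid.
#' @return Object of class `gratio_maps`: arrays `mvf`, `avf`, `g` and
#'   logical `valid`.
#' @export
compute_gratio <- function(mvf, avf, avf_floor = 1e-3) {
  check_same_grid(mvf, avf, "MVF and AVF maps")
  valid <- is.finite(mvf) & is.finite(avf) & avf > avf_floor & mvf >= 0
  g <- array(NA_real_, dim = dim(mvf))
  g[valid] <- (1 + mvf[valid] / avf[valid])^(-0.5)
  structure(list(mvf = mvf, avf = avf, g = g, valid = valid,
                 avf_floor = avf_floor),
            class = "gratio_maps")
}

#' @export
print.gratio_maps <- function(x, ...) {
  cat("<gratio_maps> valid voxels:", sum(x$valid),
      "| AVF floor:", x$avf_floor, "\n")
  v <- x$g[x$valid]
  if (length(v)) {
    cat(sprintf("  g median %.4f (IQR %.4f-%.4f)\n", stats::median(v),
                stats::quantile(v, .25), stats::quantile(v, .75)))
  }
  invisible(x)
}

#' Regional summary of a g-ratio map
#'
#' Median, interquartile range, voxel count and a fixed-bin histogram of the
#' valid in-mask g-ratio values. All regions share the same bin edges
#' (default 80 bins over \[0.40, 0.80\]) so lesion and NAWM histograms are
#' directly comparable; values outside the bin range still contribute to
#' the median/IQR but not to the histogram counts.
#'
#' @param g g-ratio array (or a `gratio_maps` object, in which case
#'   `valid` is taken from it).
#' @param valid Logical validity array (ignored when `g` is `gratio_maps`).
#' @param mask Logical region mask.
#' @param region Region label, e.g. `"WML"` or `"NAWM"`.
#' @param breaks Histogram bin edges.
#' @return Object of class `regional_summary`: `region`, `median_g`, `iqr`
#'   (length-2), `n_voxels`, `histogram` (`list(breaks, counts)`).
#' @export
regional_summary <- function(g, valid = NULL, mask, region = "region",
                             breaks = seq(0.40, 0.80, length.out = 81)) {
  if (inherits(g, "gratio_maps")) {
    valid <- g$valid
    g <- g$g
  }
  if (is.null(valid)) valid <- is.finite(g)
  mask <- as_mask(mask, g)
  vals <- g[mask & valid]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    stop("no valid voxels in region '", region, "'")
  }
  inside <- vals[vals >= breaks[1] & vals <= breaks[length(breaks)]]
  counts <- if (length(inside)) {
    hist(inside, breaks = breaks, plot = FALSE)$counts
  } else {
    integer(length(breaks) - 1)
  }
  structure(list(
    region = region,
    median_g = stats::median(vals),
    iqr = unname(stats::quantile(vals, c(0.25, 0.75))),
    n_voxels = length(vals),
    histogram = list(breaks = breaks, counts = counts)
  ), class = "regional_summary")
}

#' @export
print.regional_summary <- function(x, ...) {
  cat(sprintf("<regional_summary> %s: median g %.4f (IQR %.4f-%.4f), n = %d\n",
              x$region, x$median_g, x$iqr[1], x$iqr[2], x$n_voxels))
  invisible(x)
}

#' Run the full g-ratio mapping pipeline on one simulated study
#'
#' Chains MT relaxometry, NODDI fitting, MVF/AVF computation and the
#' aggregate g-ratio map for a phantom study produced by
#' [simulate_phantom()], and summarizes the lesion and NAWM regions.
#' Calibration uses the supplied `k`; pass the output of [calibrate_k()] on
#' control data, or a known ground-truth constant for recovery experiments.
#'
#' @param study Output of [simulate_phantom()].
#' @param k MTsat-to-MVF scaling constant.
#' @param mask Logical fit mask; defaults to the white-matter mask.
#' @param method MT relaxometry estimator path (see [fit_relaxometry()]).
#' @param noddi_control A [noddi_fit_control()].
#' @return List with `relaxometry`, `noddi`, `gratio`, and `summary`
#'   (named list of [regional_summary()]s for `wml` and `nawm`).
#' @export
run_gratio_pipeline <- function(study, k, mask = NULL,
                                method = "small_angle",
                                noddi_control = noddi_fit_control()) {
  if (is.null(mask)) mask <- study$masks$wm
  relax <- fit_relaxometry(study$volumes$pdw, study$volumes$t1w,
                           study$volumes$mtw, study$protocol,
                           mask = mask, method = method)
  noddi <- fit_noddi(study$volumes$dwi, study$protocol, mask = mask,
                     control = noddi_control)
  mvf <- compute_mvf(relax$delta_app, k, mask = mask & relax$valid)
  avf <- compute_avf(mvf, noddi$viso, noddi$vic)
  gr <- compute_gratio(mvf, avf)
  gr$valid <- gr$valid & relax$valid & noddi$valid
  summ <- list(
    wml = regional_summary(gr$g, gr$valid, study$masks$wml, "WML"),
    nawm = regional_summary(gr$g, gr$valid, study$masks$nawm, "NAWM")
  )
  list(relaxometry = relax, noddi = noddi, gratio = gr, summary = summ)
}
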