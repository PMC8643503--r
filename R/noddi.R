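## Deterministic three-compartment NODDI fit: per-voxel normalization by the
## mean b=0 signal, fibre direction from the principal eigenvector of a
## log-linear tensor fit on the low-b shell, exhaustive initialization on a
## fixed (viso, vic, odi) lattice, then bounded Levenberg-Marquardt
## refinement of the three fractions with the direction held fixed.

#' Fit control settings for the NODDI fitter
#'
#' @param viso_grid,vic_grid,odi_grid Initialization lattice values.
#' @param odi_bounds Lower/upper refinement bounds on the orientation
#'   dispersion index.
#' @param dti_bmax Maximum b-value (s/mm^2) of entries used for the
#'   log-linear tensor fit that supplies the fibre direction.
#' @param max_iter Maximum Levenberg-Marquardt iterations per voxel.
#' @return A list of class `noddi_fit_control`.
#' @export
noddi_fit_control <- function(viso_grid = seq(0.05, 0.95, by = 0.1),
                              vic_grid = seq(0.05, 0.95, by = 0.1),
                              odi_grid = c(0.04, 0.16, 0.36, 0.64, 1.0),
                              odi_bounds = c(0.01, 1),
                              dti_bmax = 1200,
                              max_iter = 50L) {
  structure(list(viso_grid = viso_grid, vic_grid = vic_grid,
                 odi_grid = odi_grid, odi_bounds = odi_bounds,
                 dti_bmax = dti_bmax, max_iter = max_iter),
            class = "noddi_fit_control")
}

## Principal diffusion direction per voxel from a log-linear tensor fit.
## smat: nvox x nvol signal matrix; returns nvox x 3 unit vectors.
tensor_directions <- function(smat, bvals, bvecs, dti_bmax) {
  use <- bvals <= dti_bmax
  if (sum(bvals[use] > 0) < 6) use <- rep(TRUE, length(bvals))  # need >= 6 DW
  b <- bvals[use]
  g <- bvecs[, use, drop = FALSE]
  X <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  pinv <- solve(crossprod(X), t(X))      # 7 x n, shared by all voxels
  logs <- log(pmax(smat[, use, drop = FALSE], .Machine$double.xmin))
  coef <- logs %*% t(pinv)               # nvox x 7
  out <- matrix(0, nrow(smat), 3)
  for (v in seq_len(nrow(smat))) {
    D <- matrix(c(coef[v, 2], coef[v, 5], coef[v, 6],
                  coef[v, 5], coef[v, 3], coef[v, 7],
                  coef[v, 6], coef[v, 7], coef[v, 4]), 3, 3)
    if (!all(is.finite(D))) {
      out[v, ] <- c(0, 0, 1)
      next
    }
    e <- eigen(D, symmetric = TRUE)
    out[v, ] <- e$vectors[, 1]
  }
  out
}

#' Fit the NODDI model to a multi-shell diffusion volume
#'
#' Estimates per-voxel isotropic signal fraction `viso`, intra-neurite
#' fraction `vic`, orientation dispersion index `odi` and fibre direction by
#' least squares on signal attenuations (unweighted; Rician bias at low SNR
#' is accepted and quantified in the package tests). The fit is fully
#' deterministic: lattice initialization followed by bounded
#' Levenberg-Marquardt refinement, with the returned objective never worse
#' than the best lattice point.
#'
#' @param dwi 4-D [signal_volume]; fourth dimension indexes the gradient
#'   table of `protocol`.
#' @param protocol An [acquisition_protocol] with at least one b = 0 entry.
#' @param mask Optional logical array restricting the fit.
#' @param control A [noddi_fit_control()].
#' @return Object of class `noddi_maps`: arrays `viso`, `vic`, `odi`,
#'   `fit_error` (residual norm), 4-D `direction`, logical `valid`.
#' @export
fit_noddi <- function(dwi, protocol, mask = NULL,
                      control = noddi_fit_control()) {
  stopifnot(inherits(dwi, "signal_volume"), inherits(protocol, "acquisition_protocol"))
  dims <- dim(dwi$data)
  if (length(dims) != 4L) stop("dwi must be a 4-D signal volume")
  if (dims[4] != length(protocol$bvals)) {
    stop("dwi has ", dims[4], " volumes but the protocol lists ",
         length(protocol$bvals), " gradient entries")
  }
  b <- protocol$bvals
  if (!any(b == 0)) stop("protocol must contain at least one b = 0 entry")
  shells <- unique(round(b[b > 0]))
  if (length(shells) < 2) {
    warning("fewer than 2 non-zero shells; viso/vic are poorly conditioned")
  }
  for (sh in shells) {
    if (sum(round(b) == sh) < 12) {
      warning("shell b=", sh, " has fewer than 12 directions")
    }
  }
  mask <- as_mask(mask, dwi)
  shape <- dims[1:3]
  nvox <- prod(shape)
  smat <- matrix(dwi$data, nrow = nvox, ncol = dims[4])
  s0 <- rowMeans(smat[, b == 0, drop = FALSE])
  vox <- which(as.vector(mask))
  valid <- as.vector(mask) & is.finite(s0) & s0 > 0
  fit_vox <- which(valid)

  viso <- array(NA_real_, shape)
  vic <- array(NA_real_, shape)
  odi <- array(NA_real_, shape)
  ferr <- array(NA_real_, shape)
  dir4 <- array(NA_real_, c(shape, 3))
  if (length(fit_vox) == 0) {
    return(structure(list(viso = viso, vic = vic, odi = odi,
                          fit_error = ferr, direction = dir4,
                          valid = array(valid, shape)),
                     class = "noddi_maps"))
  }

  dirs <- tensor_directions(smat[fit_vox, , drop = FALSE], b, protocol$bvecs,
                            control$dti_bmax)

  ## shared precomputation
  quad <- watson_quadrature()
  l <- seq(0, quad$lmax, 2)
  scale_l <- (2 * l + 1) / 2
  J <- stick_coefs(b * protocol$d_parallel, quad)        # L x nvol
  a_iso <- exp(-b * protocol$d_iso)
  d_par <- protocol$d_parallel

  ## lattice pieces independent of the voxel
  f_grid <- watson_coefs(odi_to_kappa(control$odi_grid), quad)  # L x n_odi
  n_odi <- length(control$odi_grid)
  n_vic <- length(control$vic_grid)
  n_viso <- length(control$viso_grid)
  combos <- expand.grid(iv = seq_len(n_viso), ic = seq_len(n_vic),
                        io = seq_len(n_odi))

  refine_one <- function(y, Bmat, ct2, start) {
    resid_fun <- function(par) {
      fl <- drop(watson_coefs(odi_to_kappa(par[3]), quad))
      a_ic <- drop(Bmat %*% fl)
      a_ec <- exp(-b * d_par * ((1 - par[2]) + par[2] * ct2))
      (1 - par[1]) * (par[2] * a_ic + (1 - par[2]) * a_ec) +
        par[1] * a_iso - y
    }
    fit <- minpack.lm::nls.lm(
      par = start, fn = resid_fun,
      lower = c(0, 0, control$odi_bounds[1]),
      upper = c(1, 1, control$odi_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = control$max_iter)
    )
    list(par = fit$par, rss = fit$deviance)
  }

  for (i in seq_along(fit_vox)) {
    v <- fit_vox[i]
    y <- smat[v, ] / s0[v]
    mu <- dirs[i, ]
    ct <- as.numeric(crossprod(protocol$bvecs, mu))
    ct[b == 0] <- 0
    Pg <- legendre_even(ct, quad$lmax)
    Bmat <- Pg * t(J) * rep(scale_l, each = length(b))    # nvol x L
    ct2 <- ct^2

    A_ic <- Bmat %*% f_grid                               # nvol x n_odi
    A_ec <- exp(outer(-b * d_par, rep(1, n_vic)) *
                  (rep(1, length(b)) %o% (1 - control$vic_grid) +
                     ct2 %o% control$vic_grid))           # nvol x n_vic
    ## residual sum of squares over the whole lattice
    rss <- numeric(nrow(combos))
    for (io in seq_len(n_odi)) for (ic in seq_len(n_vic)) {
      inner <- control$vic_grid[ic] * A_ic[, io] +
        (1 - control$vic_grid[ic]) * A_ec[, ic]
      sel <- which(combos$io == io & combos$ic == ic)
      pred <- outer(inner, 1 - control$viso_grid[combos$iv[sel]]) +
        outer(a_iso, control$viso_grid[combos$iv[sel]])
      rss[sel] <- colSums((pred - y)^2)
    }
    best <- which.min(rss)
    start <- c(control$viso_grid[combos$iv[best]],
               control$vic_grid[combos$ic[best]],
               control$odi_grid[combos$io[best]])
    ref <- refine_one(y, Bmat, ct2, start)
    if (!is.finite(ref$rss) || ref$rss > rss[best]) {
      ref <- list(par = start, rss = rss[best])   # refinement must not regress
    }
    viso[v] <- ref$par[1]
    vic[v] <- ref$par[2]
    odi[v] <- ref$par[3]
    ferr[v] <- sqrt(ref$rss)
    ijk <- arrayInd(v, shape)
    dir4[ijk[1], ijk[2], ijk[3], ] <- mu
  }

  structure(list(viso = viso, vic = vic, odi = odi, fit_error = ferr,
                 direction = dir4, valid = array(valid, shape)),
            class = "noddi_maps")
}

#' @export
print.noddi_maps <- function(x, ...) {
  cat("<noddi_maps> fitted voxels:", sum(x$valid), "\n")
  for (nm in c("viso", "vic", "odi", "fit_error")) {
    v <- x[[nm]][x$valid]
    if (length(v)) {
      cat(sprintf("  %-9s median %.4g (IQR %.4g-%.4g)\n", nm,
                  stats::median(v), stats::quantile(v, .25),
                  stats::quantile(v, .75)))
    }
  }
  invisible(x)
}
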