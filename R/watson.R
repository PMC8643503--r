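## Shared NODDI signal kernel.
##
## The intra-neurite compartment is a stick (zero perpendicular diffusivity)
## whose orientation is Watson-distributed about the fibre direction mu with
## concentration kappa. Its orientation-averaged attenuation is the spherical
## convolution of the Watson density with the stick response
## exp(-b d_par (g.n)^2). Both factors are axially symmetric, so by
## Funk-Hecke the convolution reduces to a Legendre series
##
##   A_ic(b, cos_theta) = sum_{l even} (2l+1)/2 * f_l(kappa) * J_l(b d_par)
##                         * P_l(cos_theta),
##   f_l(kappa) = int_-1^1 e^{kappa t^2} P_l(t) dt / int_-1^1 e^{kappa t^2} dt,
##   J_l(a)     = int_-1^1 e^{-a t^2} P_l(t) dt,
##
## with cos_theta the cosine between gradient and mean fibre direction.
## Both 1-D integrals are evaluated by Gauss-Legendre quadrature over the
## polar angle (128 nodes). Because the stick kernel is angularly smooth at
## b-values used in vivo, the product f_l * J_l decays fast and truncation
## at l = 24 is accurate to machine precision for kappa up to ~64
## (orientation dispersion index down to ~0.01).

.watson_env <- new.env(parent = emptyenv())

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  cached <- .watson_env[[key]]
  if (!is.null(cached)) return(cached)
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  .watson_env[[key]] <- out
  out
}

## Even-degree Legendre polynomials P_0, P_2, ..., P_lmax evaluated at t;
## returns length(t) x (lmax/2 + 1) matrix.
legendre_even <- function(t, lmax = 24L) {
  t <- as.numeric(t)
  out <- matrix(0, length(t), lmax / 2 + 1)
  out[, 1] <- 1
  if (lmax < 2) return(out)
  pm2 <- rep(1, length(t))
  pm1 <- t
  for (l in 2:lmax) {
    p <- ((2 * l - 1) * t * pm1 - (l - 1) * pm2) / l
    if (l %% 2 == 0) out[, l / 2 + 1] <- p
    pm2 <- pm1
    pm1 <- p
  }
  out
}

## Quadrature rule + Legendre matrix shared by the coefficient integrals.
watson_quadrature <- function(n_nodes = 128L, lmax = 24L) {
  key <- paste0("wq", n_nodes, "_", lmax)
  cached <- .watson_env[[key]]
  if (!is.null(cached)) return(cached)
  q <- gauss_legendre(n_nodes)
  out <- list(x = q$x, w = q$w, P = legendre_even(q$x, lmax), lmax = lmax)
  .watson_env[[key]] <- out
  out
}

## Normalized even-Legendre coefficients f_l of the Watson density
## (f_0 = 1 by construction). exp(kappa(t^2-1)) scaling keeps large kappa
## finite. Vectorized over kappa: returns (lmax/2+1) x length(kappa).
watson_coefs <- function(kappa, quad = watson_quadrature()) {
  kappa <- as.numeric(kappa)
  W <- exp(outer(quad$x^2 - 1, kappa)) * quad$w   # nodes x kappas
  num <- crossprod(quad$P, W)                     # coeffs x kappas
  sweep(num, 2, colSums(W), "/")
}

## Stick response coefficients J_l(a), a = b * d_parallel (vector a allowed):
## returns (lmax/2+1) x length(a).
stick_coefs <- function(a, quad = watson_quadrature()) {
  a <- as.numeric(a)
  K <- exp(outer(-quad$x^2, a)) * quad$w
  crossprod(quad$P, K)
}

## Orientation dispersion index <-> Watson concentration.
## odi = (2/pi) atan(1/kappa), kappa = 1/tan(pi odi / 2).
#' Convert between orientation dispersion index and Watson concentration
#'
#' `odi_to_kappa()` maps the orientation dispersion index (ODI, in (0, 1])
#' to the Watson concentration parameter kappa; `kappa_to_odi()` inverts it.
#' ODI = 1 is the isotropic limit (kappa = 0); ODI -> 0 is a coherent stick.
#'
#' @param odi,kappa Numeric vectors.
#' @return Numeric vector.
#' @export
odi_to_kappa <- function(odi) 1 / tan(pi * odi / 2)

#' @rdname odi_to_kappa
#' @export
kappa_to_odi <- function(kappa) (2 / pi) * atan(1 / kappa)

## Watson-dispersed-stick attenuation for gradient/fibre cosines ct at
## a = b * d_parallel (both vectors of common length), single kappa.
watson_stick_attenuation <- function(a, ct, kappa, quad = watson_quadrature()) {
  l <- seq(0, quad$lmax, 2)
  coef <- (2 * l + 1) / 2 * drop(watson_coefs(kappa, quad)) # per-l
  J <- stick_coefs(a, quad)                                 # l x n
  Pg <- legendre_even(ct, quad$lmax)                        # n x l
  rowSums(Pg * t(J) * rep(coef, each = length(ct)))
}

#' Predict the NODDI signal attenuation for one voxel
#'
#' Evaluates the three-compartment forward model
#' `S/S0 = (1 - viso) * (vic * A_ic + (1 - vic) * A_ec) + viso * exp(-b d_iso)`
#' for every entry of the gradient table. `A_ic` is a Watson-dispersed stick
#' and `A_ec` a zeppelin aligned with the fibre direction whose perpendicular
#' diffusivity is tortuosity-coupled, `d_perp = d_parallel * (1 - vic)`.
#' This is the same kernel the phantom simulator and the fitter use.
#'
#' @param viso Isotropic (free-water) signal fraction in \[0, 1\].
#' @param vic Intra-neurite signal fraction in \[0, 1\].
#' @param odi Orientation dispersion index in (0, 1\].
#' @param direction Length-3 fibre direction (normalized internally).
#' @param protocol An [acquisition_protocol].
#' @return Numeric vector of attenuations in \[0, 1\], one per gradient entry.
#' @export
predict_noddi_signal <- function(viso, vic, odi, direction, protocol) {
  stopifnot(viso >= 0, viso <= 1, vic >= 0, vic <= 1, odi > 0, odi <= 1)
  mu <- direction / sqrt(sum(direction^2))
  b <- protocol$bvals
  ct <- as.numeric(crossprod(protocol$bvecs, mu))
  ct[b == 0] <- 0   # direction is meaningless at b = 0 (A_ic = 1 there anyway)
  noddi_attenuation(b, ct, viso, vic, odi,
                    d_par = protocol$d_parallel, d_iso = protocol$d_iso)
}

## Core attenuation kernel on precomputed cosines; vectorized over the
## gradient table for a single parameter set.
noddi_attenuation <- function(b, ct, viso, vic, odi, d_par, d_iso,
                              quad = watson_quadrature()) {
  kappa <- odi_to_kappa(odi)
  a_ic <- watson_stick_attenuation(b * d_par, ct, kappa, quad)
  d_perp <- d_par * (1 - vic)
  a_ec <- exp(-b * (d_perp + (d_par - d_perp) * ct^2))
  a_iso <- exp(-b * d_iso)
  (1 - viso) * (vic * a_ic + (1 - vic) * a_ec) + viso * a_iso
}
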