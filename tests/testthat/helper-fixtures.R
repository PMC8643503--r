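## Shared fixtures and independent oracles for the test suite. Everything
## is generated in code; no binary fixtures.

## Small, fast phantom for module tests.
small_spec <- function(snr = Inf, lesions = list(list(centre = c(8, 8, 5),
                                                      radius = 2)),
                       seed = 1L, ...) {
  phantom_spec(grid_shape = c(16, 16, 10), snr = snr, lesions = lesions,
               seed = seed, ...)
}

## Reduced gradient table so per-voxel fits stay cheap in unit tests.
small_protocol <- function() default_protocol(n_dir = 24, n_b0 = 2)

## ---- independent oracles -------------------------------------------------

## Dense 2-D spherical quadrature of the Watson-dispersed stick attenuation,
## independent of the package's Legendre-series kernel.
oracle_watson_stick <- function(a, kappa, ct, n_theta = 400, n_phi = 512) {
  i <- seq_len(n_theta - 1)
  bdiag <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n_theta, n_theta)
  J[cbind(i, i + 1)] <- bdiag
  J[cbind(i + 1, i)] <- bdiag
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  st <- sqrt(pmax(0, 1 - x^2))
  sg <- sqrt(max(0, 1 - ct^2))
  W <- exp(kappa * (x^2 - 1)) * w
  num <- 0
  for (ph in phi) {
    dot <- ct * x + sg * st * cos(ph)
    num <- num + sum(W * exp(-a * dot^2))
  }
  num / (n_phi * sum(W))
}

## Brute-force voxelized sphere count.
oracle_sphere_count <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(g$x^2 + g$y^2 + g$z^2 <= radius^2)
}

## Exact Wilcoxon signed-rank p by direct enumeration (written independently
## of the package: enumerates sign vectors via integer bit masks).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(m) {
    sum(r[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
}

## Exact Mann-Whitney p by enumeration of group assignments.
oracle_mann_whitney_p <- function(a, b) {
  m <- length(a)
  n <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mid <- m * n / 2
  sel <- utils::combn(m + n, m)
  u <- colSums(matrix(r[sel], nrow = m)) - m * (m + 1) / 2
  mean(abs(u - mid) >= abs(u_obs - mid) - 1e-9)
}

## Exact Spearman p by full permutation enumeration (iterative heap
## algorithm, independent of the package's recursive generator).
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perm <- seq_len(n)
  c_ctr <- integer(n)
  rhos <- stats::cor(rx, ry[perm])
  i <- 1L
  while (i <= n) {
    if (c_ctr[i] < i - 1L) {
      j <- if (i %% 2L == 1L) 1L else c_ctr[i] + 1L
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
      rhos <- c(rhos, stats::cor(rx, ry[perm]))
      c_ctr[i] <- c_ctr[i] + 1L
      i <- 1L
    } else {
      c_ctr[i] <- 0L
      i <- i + 1L
    }
  }
  mean(abs(rhos) >= abs(rho_obs) - 1e-9)
}

## Fisher 2x2 point-probability p via explicit binomial-coefficient ratios.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  pr <- vapply(lo:hi, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
  }, numeric(1))
  pobs <- pr[tab[1, 1] - lo + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

## ---- record-level cohort fixture -----------------------------------------

## Deterministic cohort whose stratified analysis lands on the published
## contingency structure: 73 patients, 35 low-load (13 abnormal-g of whom 1
## elevated / 22 normal-g of whom 3 elevated) and 38 substantial-load
## (23 abnormal-g, 11 elevated / 15 normal-g, 2 elevated); 63 controls.
fixture_cohort <- function() {
  ## controls: symmetric around 4.5 pg/ml; elevated threshold = mean + 3 SD
  ctrl_nfl <- seq(3.5, 5.5, length.out = 63)
  thr <- mean(ctrl_nfl) + 3 * sd(ctrl_nfl)
  make_group <- function(n, abn, elev_abn, elev_norm, vol_lo, vol_hi, tag) {
    nrm <- n - abn
    g <- c(seq(0.630, 0.660, length.out = abn),    # abnormal: above cut
           seq(0.550, 0.585, length.out = nrm))    # normal: at/below cut
    elev <- c(rep(c(TRUE, FALSE), c(elev_abn, abn - elev_abn)),
              rep(c(TRUE, FALSE), c(elev_norm, nrm - elev_norm)))
    data.frame(
      subject_id = paste0(tag, seq_len(n)),
      group = "patient",
      nfl_pg_ml = ifelse(elev, thr + 4, thr - 3),
      lesion_vol_pct_icv = seq(vol_lo, vol_hi, length.out = n),
      g_wml = g,
      g_nawm = g - 0.036,
      stringsAsFactors = FALSE
    )
  }
  low <- make_group(35, abn = 13, elev_abn = 1, elev_norm = 3,
                    vol_lo = 0.05, vol_hi = 0.38, tag = "PL")
  sub <- make_group(38, abn = 23, elev_abn = 11, elev_norm = 2,
                    vol_lo = 0.62, vol_hi = 3.0, tag = "PS")
  controls <- data.frame(
    subject_id = paste0("C", seq_len(63)), group = "control",
    nfl_pg_ml = ctrl_nfl, lesion_vol_pct_icv = NA_real_,
    g_wml = NA_real_, g_nawm = NA_real_, stringsAsFactors = FALSE
  )
  rbind(low, sub, controls)
}
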