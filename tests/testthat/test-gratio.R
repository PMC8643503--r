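test_that("k calibration satisfies its algebraic identities", {
  shape <- c(4, 4, 2)
  mask <- array(TRUE, shape)
  delta <- array(0.03, shape)
  ## uniform delta, target median MVF 0.30 -> k = 10 exactly
  expect_equal(calibrate_k(delta, mask,
                           target = list(type = "median_mvf", value = 0.30)),
               10)
  ## homogeneity: scaling delta by c scales k by 1/c
  k1 <- calibrate_k(delta, mask, target = list(type = "median_mvf", value = 0.30))
  k2 <- calibrate_k(delta * 3, mask, target = list(type = "median_mvf", value = 0.30))
  expect_equal(k2, k1 / 3, tolerance = 1e-12)
  expect_error(calibrate_k(delta, array(FALSE, shape),
                           target = list(type = "median_mvf", value = 0.3)),
               "empty")
})

test_that("median-g calibration target matches a brute-force 1-D search", {
  shape <- c(5, 5, 2)
  mask <- array(TRUE, shape)
  set.seed(4)
  delta <- array(runif(prod(shape), 0.035, 0.05), shape)
  viso <- array(0.05, shape)
  vic <- array(0.36, shape)
  k <- calibrate_k(delta, mask, target = list(type = "median_g", value = 0.70),
                   viso_maps = viso, vic_maps = vic)
  ## oracle: dense grid search over k
  med_g <- function(k) {
    mvf <- pmin(pmax(k * delta[mask], 0), 1 - 1e-6)
    avf <- (1 - mvf) * (1 - viso[mask]) * vic[mask]
    median((1 + mvf / avf)^(-0.5))
  }
  ks <- seq(0.1, 20, by = 1e-3)
  k_oracle <- ks[which.min(abs(vapply(ks, med_g, numeric(1)) - 0.70))]
  expect_equal(k, k_oracle, tolerance = 2e-3)
  expect_equal(med_g(k), 0.70, tolerance = 1e-9)
})

test_that("MVF map applies the linear scaling with counted clipping", {
  shape <- c(3, 3, 1)
  delta <- array(0.03, shape)
  mvf <- compute_mvf(delta, 10)
  expect_equal(unique(as.vector(mvf)), 0.30)
  expect_equal(attr(mvf, "n_clipped"), 0L)
  expect_equal(unique(as.vector(compute_mvf(array(0, shape), 10))), 0)

  ## negative (noise) values clip to zero and are counted
  delta2 <- delta
  delta2[1, 1, 1] <- -0.01
  expect_warning(mvf2 <- compute_mvf(delta2, 10), "clipped")
  expect_equal(mvf2[1, 1, 1], 0)
  expect_equal(attr(mvf2, "n_clipped"), 1L)
  expect_error(compute_mvf(delta2, 10, strict = TRUE), "clipped")
  expect_error(compute_mvf(delta, -1), "positive")
})

test_that("AVF and g-ratio follow their closed forms", {
  shape <- c(2, 2, 1)
  as_arr <- function(x) array(x, shape)
  expect_equal(unique(as.vector(
    compute_avf(as_arr(0.3), as_arr(0.1), as_arr(0.5)))), 0.315)
  expect_equal(unique(as.vector(
    compute_avf(as_arr(0.3), as_arr(0.1), as_arr(0)))), 0)
  expect_equal(unique(as.vector(
    compute_avf(as_arr(0.3), as_arr(1), as_arr(0.5)))), 0)

  g <- compute_gratio(as_arr(0.2), as_arr(0.2))
  expect_equal(unique(g$g[g$valid]), 1 / sqrt(2))
  g1 <- compute_gratio(as_arr(0), as_arr(0.2))
  expect_equal(unique(g1$g[g1$valid]), 1)          # unmyelinated limit
  g2 <- compute_gratio(as_arr(0.3375), as_arr(0.20))
  expect_equal(unique(g2$g[g2$valid]), (1 + 0.3375 / 0.20)^(-0.5))
  expect_equal(unique(g2$g[g2$valid]), 0.610, tolerance = 5e-4)

  ## AVF at/below the floor flags invalid instead of erroring
  g3 <- compute_gratio(as_arr(0.3), as_arr(1e-4))
  expect_false(any(g3$valid))
  expect_true(all(is.na(g3$g)))
})

test_that("increasing MTsat strictly decreases g at fixed NODDI fractions", {
  deltas <- seq(0.02, 0.05, by = 0.005)
  g <- sapply(deltas, function(d) {
    mvf <- compute_mvf(array(d, c(1, 1, 1)), 10)
    avf <- compute_avf(mvf, array(0.1, c(1, 1, 1)), array(0.4, c(1, 1, 1)))
    compute_gratio(mvf, avf)$g[1, 1, 1]
  })
  expect_true(all(diff(g) < 0))
})

test_that("mvf + avf never exceeds one on valid voxels", {
  set.seed(9)
  shape <- c(6, 6, 3)
  mvf <- suppressWarnings(  # heavy clipping is intended in this stress draw
    compute_mvf(array(runif(prod(shape), -0.01, 0.12), shape), 10))
  avf <- compute_avf(mvf, array(runif(prod(shape)), shape),
                     array(runif(prod(shape)), shape))
  g <- compute_gratio(mvf, avf)
  expect_true(all((mvf + avf)[g$valid] <= 1 + 1e-9))
  expect_true(all(g$g[g$valid] > 0 & g$g[g$valid] <= 1))
})

test_that("regional summary matches a sort-based oracle with shared bins", {
  set.seed(2)
  shape <- c(8, 8, 4)
  g <- array(runif(prod(shape), 0.5, 0.7), shape)
  mask <- array(FALSE, shape)
  mask[2:6, 2:6, 2:3] <- TRUE
  valid <- array(TRUE, shape)
  valid[2, 2, 2] <- FALSE
  rs <- regional_summary(g, valid, mask, "WML")
  vals <- sort(g[mask & valid])
  n <- length(vals)
  med_oracle <- if (n %% 2 == 1) vals[(n + 1) / 2] else
    mean(vals[n / 2 + 0:1])                         # midpoint convention
  expect_equal(rs$median_g, med_oracle)
  expect_equal(rs$n_voxels, n)
  expect_equal(sum(rs$histogram$counts), n)
  expect_equal(rs$histogram$breaks, seq(0.40, 0.80, length.out = 81))
  expect_gte(rs$median_g, rs$histogram$breaks[1])
  expect_lte(rs$median_g, rs$histogram$breaks[81])

  ## uniform region: degenerate median and IQR
  gu <- array(0.6, shape)
  rsu <- regional_summary(gu, NULL, mask, "NAWM")
  expect_equal(rsu$median_g, 0.6)
  expect_equal(rsu$iqr, c(0.6, 0.6))

  ## empty region errors with its label
  expect_error(regional_summary(g, array(FALSE, shape), mask, "WML"), "WML")
})

test_that("noiseless end-to-end phantom recovers the closed-form medians", {
  proto <- small_protocol()
  st <- simulate_phantom(small_spec(snr = Inf), proto)
  res <- run_gratio_pipeline(st, k = st$gt$k_true, method = "exact")
  expect_equal(res$summary$wml$median_g, 0.610, tolerance = 2e-3)
  expect_equal(res$summary$nawm$median_g, 0.570, tolerance = 2e-3)
})
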