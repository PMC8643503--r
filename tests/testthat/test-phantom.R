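test_that("ground-truth construction obeys the mask algebra and geometry", {
  spec <- small_spec(lesions = list())
  truth <- make_ground_truth(spec)
  expect_false(any(truth$masks$wml))
  expect_identical(truth$masks$nawm, truth$masks$wm)
  expect_true(all(truth$masks$wm[truth$masks$wm] & truth$masks$icv[truth$masks$wm]))

  ## voxel count of a discrete sphere matches brute-force enumeration
  spec2 <- phantom_spec(grid_shape = c(32, 32, 16),
                        lesions = list(list(centre = c(16, 16, 8), radius = 3)))
  truth2 <- make_ground_truth(spec2)
  expect_identical(sum(truth2$masks$wml), oracle_sphere_count(3))
  expect_true(all(truth2$masks$nawm == (truth2$masks$wm & !truth2$masks$wml)))

  ## a lesion placed outside WM is rejected by index
  bad <- phantom_spec(grid_shape = c(16, 16, 10),
                      lesions = list(list(centre = c(2, 2, 2), radius = 2)))
  expect_error(make_ground_truth(bad), "lesion 1")
})

test_that("lesion preset with lower MTsat implies a higher true g-ratio", {
  spec <- small_spec()
  truth <- make_ground_truth(spec)
  g_true <- function(preset, k) {
    mvf <- k * preset$delta_app
    avf <- (1 - mvf) * (1 - preset$viso) * preset$vic
    (1 + mvf / avf)^(-0.5)
  }
  expect_lt(spec$lesion$delta_app, spec$nawm$delta_app)
  expect_gt(g_true(spec$lesion, spec$k_true), g_true(spec$nawm, spec$k_true))
  ## the default presets encode the lesion/NAWM anchors 0.610 / 0.570
  expect_equal(g_true(spec$lesion, spec$k_true), 0.610, tolerance = 1e-3)
  expect_equal(g_true(spec$nawm, spec$k_true), 0.570, tolerance = 1e-3)
})

test_that("SPGR forward model matches its closed form and scales linearly", {
  proto <- small_protocol()
  ## single voxel, direct closed-form evaluation
  a <- 6 * pi / 180
  E <- exp(-1 * 0.020)
  expect_equal(gratiokit:::spgr_signal(1000, 1, a, 0.020),
               1000 * sin(a) * (1 - E) / (1 - cos(a) * E))

  spec <- small_spec()
  truth <- make_ground_truth(spec)
  vols <- simulate_spgr(truth$gt, proto)

  ## delta = 0 everywhere -> MTw equals the PDw forward model at MTw settings
  gt0 <- truth$gt
  gt0$delta_app[] <- 0
  vols0 <- simulate_spgr(gt0, proto)
  ref <- gratiokit:::spgr_signal(gt0$a_true, gt0$r1_true,
                     proto$spgr$mtw$flip_rad, proto$spgr$mtw$tr_s)
  expect_equal(vols0$mtw$data, ref, tolerance = 1e-12)

  ## doubling the amplitude doubles all three signals voxel-wise
  gt2 <- truth$gt
  gt2$a_true <- 2 * gt2$a_true
  vols2 <- simulate_spgr(gt2, proto)
  for (nm in c("pdw", "t1w", "mtw")) {
    expect_equal(vols2[[nm]]$data, 2 * vols[[nm]]$data, tolerance = 1e-12)
  }

  ## the MT saturation strictly reduces the MTw signal in saturated voxels
  expect_true(all((vols$mtw$data < vols0$mtw$data)[truth$gt$delta_app > 0]))
})

test_that("DWI forward model honours its limiting cases", {
  proto <- small_protocol()
  spec <- small_spec()
  truth <- make_ground_truth(spec)
  dwi <- simulate_dwi(truth$gt, proto)

  ## b = 0 entries equal S0 = a_true
  b0 <- which(proto$bvals == 0)
  for (i in b0) {
    expect_equal(dwi$data[, , , i], truth$gt$a_true, tolerance = 1e-12)
  }
  ## attenuations in [0, 1]
  att <- sweep(matrix(dwi$data, ncol = length(proto$bvals)), 1,
               as.vector(truth$gt$a_true), "/")
  att <- att[is.finite(att)]
  expect_true(all(att >= 0 & att <= 1 + 1e-12))

  ## pure free water at b = 1000: attenuation exp(-3)
  p1 <- acquisition_protocol(
    spgr = list(pdw = list(flip_deg = 6, tr_s = .025),
                t1w = list(flip_deg = 21, tr_s = .011),
                mtw = list(flip_deg = 6, tr_s = .025)),
    bvals = c(0, 1000), bvecs = cbind(c(0, 0, 0), c(0, 0, 1)),
    d_iso = 3.0e-3)
  expect_equal(predict_noddi_signal(1, 0.5, 0.5, c(0, 0, 1), p1)[2],
               exp(-3), tolerance = 1e-12)

  ## negative b-value rejected at protocol construction
  expect_error(acquisition_protocol(
    spgr = list(pdw = list(flip_deg = 6, tr_s = .025),
                t1w = list(flip_deg = 21, tr_s = .011),
                mtw = list(flip_deg = 6, tr_s = .025)),
    bvals = c(0, -5), bvecs = cbind(c(0, 0, 0), c(0, 0, 1))),
    "non-negative")
})

test_that("Watson-stick kernel agrees with dense numerical integration", {
  d_par <- 1.7e-3
  for (kappa in c(0.5, 3.1, 16, 64)) {
    for (b in c(700, 2000)) {
      for (ct in c(0, 0.5, 1)) {
        expect_equal(
          gratiokit:::watson_stick_attenuation(b * d_par, ct, kappa),
          oracle_watson_stick(b * d_par, kappa, ct),
          tolerance = 1e-9
        )
      }
    }
  }
  ## coherent-stick limit: no attenuation perpendicular to the fibre
  expect_equal(
    gratiokit:::watson_stick_attenuation(2000 * d_par, 0, odi_to_kappa(0.01)),
    oracle_watson_stick(2000 * d_par, odi_to_kappa(0.01), 0),
    tolerance = 1e-9
  )
  expect_gt(gratiokit:::watson_stick_attenuation(2000 * d_par, 0,
                                                 odi_to_kappa(0.01)), 0.97)
})

test_that("Rician noise has the advertised distribution and determinism", {
  vol <- signal_volume(array(0, dim = c(40, 50, 50)))
  noisy <- add_rician_noise(vol, snr = 10, reference_signal = 100, seed = 42)
  ## zero-signal voxels follow a Rayleigh law with mean sigma*sqrt(pi/2)
  sigma <- 100 / 10
  expect_equal(mean(noisy$data), sigma * sqrt(pi / 2),
               tolerance = 3 / sqrt(length(vol$data)))  # ~3 MC sigmas

  ## snr = Inf is the identity
  vol2 <- signal_volume(array(runif(125), dim = c(5, 5, 5)))
  expect_identical(add_rician_noise(vol2, Inf, 100, seed = 1)$data, vol2$data)

  ## same seed twice -> bit-identical; different seed -> different
  n1 <- add_rician_noise(vol2, 20, 1, seed = 7)
  n2 <- add_rician_noise(vol2, 20, 1, seed = 7)
  n3 <- add_rician_noise(vol2, 20, 1, seed = 8)
  expect_identical(n1$data, n2$data)
  expect_false(identical(n1$data, n3$data))
})

test_that("noise draws do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(add_rician_noise(signal_volume(array(1, c(3, 3, 3))), 10, 1, seed = 5))
  expect_identical(runif(1), before)
})

test_that("FLAIR simulator produces the configured lesion contrast", {
  spec <- small_spec()
  truth <- make_ground_truth(spec)

  ## zero contrast: lesion and NAWM distributions identical in expectation
  fl0 <- simulate_flair(truth$gt, truth$masks, contrast = 0, seed = 3)
  expect_lt(abs(mean(fl0$data[truth$masks$wml]) -
                  mean(fl0$data[truth$masks$nawm])), 3 * 10 / sqrt(30))

  ## empty lesion set: a pure NAWM-statistics image inside WM
  truth2 <- make_ground_truth(small_spec(lesions = list()))
  fl2 <- simulate_flair(truth2$gt, truth2$masks, contrast = 5, seed = 3)
  expect_equal(mean(fl2$data[truth2$masks$wm]), 100, tolerance = 2)

  ## configured contrast shifts the lesion mean by contrast * noise_sd
  fl5 <- simulate_flair(truth$gt, truth$masks, contrast = 5, seed = 3)
  expect_equal(mean(fl5$data[truth$masks$wml]) - mean(fl5$data[truth$masks$nawm]),
               50, tolerance = 10)
})

test_that("phantom study simulation is bit-identical under a fixed seed", {
  proto <- small_protocol()
  s1 <- simulate_phantom(small_spec(snr = 30, seed = 11), proto)
  s2 <- simulate_phantom(small_spec(snr = 30, seed = 11), proto)
  for (nm in names(s1$volumes)) {
    expect_identical(s1$volumes[[nm]]$data, s2$volumes[[nm]]$data)
  }
  ## ground-truth fractions stay in [0, 1]
  for (nm in c("viso", "vic", "odi")) {
    expect_true(all(s1$gt[[nm]] >= 0 & s1$gt[[nm]] <= 1))
  }
})
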