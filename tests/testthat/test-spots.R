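test_that("the DoG detector recovers well-separated blobs and nothing else", {
  # constant image: no spots
  flat <- list(data = array(7, c(20, 20, 12)), voxel_size_um = c(2, 2, 5))
  expect_equal(nrow(detect_spots(flat, spot_params())), 0L)
  expect_error(detect_spots(list(data = array(0, c(4, 4, 4)))),
               "voxel-size")
  # five well-separated blobs above threshold
  set.seed(19)
  truth <- data.frame(x_um = c(20, 60, 30, 70, 45),
                      y_um = c(20, 50, 70, 75, 40),
                      z_um = c(30, 60, 90, 30, 75),
                      intensity = c(500, 800, 650, 700, 550))
  st <- simulate_nuclei_stack(truth, shape = c(48, 48, 24),
                              voxel_size_um = c(2, 2, 5),
                              blob_sigma_um = c(1.7, 3.4),
                              background = 100, noise_sd = 5)
  sp <- detect_spots(st, spot_params(intensity_threshold = 200))
  expect_equal(nrow(sp), 5L)
  # each detection within one voxel of its ground-truth nucleus
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((sp$x_um - truth$x_um[i])^2 + (sp$y_um - truth$y_um[i])^2 +
                ((sp$z_um - truth$z_um[i]) / 2.5)^2)
    expect_lt(min(d), 5.5)
  }
  # a blob whose peak sits below the threshold is dropped
  dim_st <- simulate_nuclei_stack(
    data.frame(x_um = 40, y_um = 40, z_um = 60, intensity = 30),
    shape = c(40, 40, 24), voxel_size_um = c(2, 2, 5), background = 100)
  expect_equal(nrow(detect_spots(dim_st,
                                 spot_params(intensity_threshold = 200))), 0L)
})

test_that("greedy matching is exact on trivial geometries", {
  a <- data.frame(x_um = 10, y_um = 10, z_um = 10)
  m <- match_dual(a, a)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$dist, 0)
  b <- data.frame(x_um = 20, y_um = 10, z_um = 10)  # 10 um away in XY
  m2 <- match_dual(a, b, match_params(max_distance_um = 4))
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_lumbar, 1L)
  expect_equal(m2$unmatched_cervical, 1L)
})

test_that("anisotropic scaling relaxes axial offsets only", {
  a <- data.frame(x_um = 0, y_um = 0, z_um = 0)
  b <- data.frame(x_um = 0, y_um = 0, z_um = 6)
  expect_equal(nrow(match_dual(a, b, match_params(4, "euclidean"))$pairs), 0L)
  # z offset halved into XY-equivalent units: 6 um -> 3 um < 4 um
  expect_equal(nrow(match_dual(a, b, match_params(4, "anisotropic"))$pairs),
               1L)
  # and an XY offset is unaffected by the metric choice
  bx <- data.frame(x_um = 6, y_um = 0, z_um = 0)
  expect_equal(nrow(match_dual(a, bx, match_params(4, "anisotropic"))$pairs),
               0L)
})

test_that("match cardinality is bounded and monotone in the threshold", {
  set.seed(29)
  n <- 150
  a <- data.frame(x_um = runif(n, 0, 150), y_um = runif(n, 0, 150),
                  z_um = runif(n, 0, 80))
  b <- data.frame(x_um = runif(n, 0, 150), y_um = runif(n, 0, 150),
                  z_um = runif(n, 0, 80))
  prev <- -1L
  for (thr in c(1, 2, 4, 8, 16)) {
    m <- match_dual(a, b, match_params(max_distance_um = thr))
    expect_lte(nrow(m$pairs), n)
    expect_gte(nrow(m$pairs), prev)
    expect_true(all(m$pairs$dist <= thr))
    # one-to-one: no index reused, pairs + unmatched partition each set
    expect_false(any(duplicated(m$pairs$i)))
    expect_false(any(duplicated(m$pairs$j)))
    expect_setequal(c(m$pairs$i, m$unmatched_lumbar), seq_len(n))
    expect_setequal(c(m$pairs$j, m$unmatched_cervical), seq_len(n))
    prev <- nrow(m$pairs)
  }
})

test_that("co-label rates are exact on degenerate inputs", {
  a <- data.frame(x_um = c(1, 10, 20), y_um = 0, z_um = 0,
                  region = c("CST", "CST", "RN"))
  m_all <- match_dual(a, a)
  r <- colabel_rate(m_all, a)
  expect_equal(r$rate[r$region == "overall"], 1.0)
  expect_equal(r$rate[r$region == "CST"], 1.0)
  far <- transform(a, x_um = x_um + 100)
  m_none <- match_dual(a, far)
  r0 <- colabel_rate(m_none, a)
  expect_equal(r0$rate[r0$region == "overall"], 0.0)
})

test_that("matching recovers the generator's dual probability", {
  atl <- small_atlas(2, shape = c(40, 40, 40))
  p_true <- c(0.45, 0.15)
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = 400,
                         dual_probability = p_true,
                         cervical_mean_count = 250),
    arms = data.frame(condition = "uninjured", severity = "none",
                      n_animals = 4),
    seed = 37)
  co <- simulate_cohort(des, atl)
  per_reg <- matrix(0, 2, 2)  # dual, total per region
  for (aid in names(co$animals)) {
    lum <- co$animals[[aid]]$lumbar
    cer <- co$animals[[aid]]$cervical
    m <- match_dual(lum, cer)
    # sub-resolution jitter: every true dual cell is matched, nothing else
    matched <- logical(nrow(lum)); matched[m$pairs$i] <- TRUE
    expect_identical(matched, lum$dual)
    cl <- colabel_rate(m, lum)
    for (r in 1:2) {
      per_reg[r, 1] <- per_reg[r, 1] + cl$n_dual[cl$region == r]
      per_reg[r, 2] <- per_reg[r, 2] + cl$n_lumbar[cl$region == r]
    }
  }
  for (r in 1:2) {
    ci <- binom.test(per_reg[r, 1], per_reg[r, 2],
                     conf.level = 0.99)$conf.int
    expect_true(ci[1] <= p_true[r] && p_true[r] <= ci[2])
  }
})

test_that("intensity contrasts reflect the dimming model", {
  atl <- small_atlas(2, shape = c(40, 40, 40))
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = 500, dual_probability = 0.5,
                         cervical_mean_count = 400),
    intensity_model = list(dual_cervical_dimming = 0.5),
    arms = data.frame(condition = "uninjured", severity = "none",
                      n_animals = 2),
    seed = 41)
  co <- simulate_cohort(des, atl)
  lum <- co$animals[[1]]$lumbar; cer <- co$animals[[1]]$cervical
  m <- match_dual(lum, cer)
  ic <- intensity_contrast(m, lum, cer)
  cerv <- ic$contrast[ic$contrast$channel == "cervical", ]
  # lognormal geometric-mean ratio recovers the dimming factor
  expect_lt(abs(cerv$ratio - 0.5), 0.06)
  expect_lt(cerv$p, 1e-6)
  # lumbar channel: no dimming, contrast consistent with zero
  lumr <- ic$contrast[ic$contrast$channel == "lumbar", ]
  expect_gt(lumr$p, 0.01)
  # undefined flag when one group is (nearly) empty
  tiny <- data.frame(x_um = 1, y_um = 1, z_um = 1, intensity = 5)
  m0 <- match_dual(tiny, transform(tiny, x_um = 500))
  ic0 <- intensity_contrast(m0, tiny, tiny)
  expect_true(all(ic0$contrast$undefined))
})

test_that("dropout is the identity at q=1, zero at q=0+, and exact on the constructed dim-dual set", {
  # constructed set: half the lumbar nuclei are dual, and every dual cell
  # carries the dimmest cervical label
  n <- 40
  lum <- data.frame(x_um = seq_len(n) * 20, y_um = 0, z_um = 0,
                    intensity = 100)
  dual_idx <- seq_len(n / 2)
  cer <- data.frame(x_um = c(lum$x_um[dual_idx], 5000 + seq_len(n / 2) * 20),
                    y_um = 0, z_um = 0,
                    intensity = c(rep(1, n / 2),      # dual: dimmest
                                  rep(1000, n / 2)))  # cervical-only: bright
  dc <- dropout_curve(lum, cer, match_params(),
                      retain_fractions = c(1, 0.5, 1e-9))
  expect_equal(dc$dual_rate[dc$fraction == 1], 0.5)
  expect_equal(dc$relative_change_pct[dc$fraction == 1], 0)
  expect_equal(dc$dual_rate[dc$fraction == 0.5], 0)
  expect_equal(dc$relative_change_pct[dc$fraction == 0.5], -100)
  expect_equal(dc$dual_rate[dc$fraction == 1e-9], 0)
  expect_true(dc$empty[dc$fraction == 1e-9])
})
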