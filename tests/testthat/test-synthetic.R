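test_that("a fixed seed reproduces the cohort byte for byte", {
  atl <- small_atlas()
  des <- small_design(seed = 13)
  co1 <- simulate_cohort(des, atl)
  co2 <- simulate_cohort(des, atl)
  expect_identical(co1, co2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  f <- list.files(d1)
  expect_setequal(f, list.files(d2))
  for (fn in f)
    expect_identical(readBin(file.path(d1, fn), "raw", 1e6),
                     readBin(file.path(d2, fn), "raw", 1e6))
})

test_that("design validation rejects out-of-range parameters", {
  reg <- data.frame(id = 1:2, mean_count = c(10, 10),
                    dual_probability = c(0.5, 0.5))
  expect_error(cohort_design(transform(reg, dual_probability = c(0.5, 1.2))),
               "dual_probability")
  expect_error(cohort_design(reg, dispersion = 0), "dispersion")
  expect_error(cohort_design(reg,
    intensity_model = list(dual_cervical_dimming = 0)), "dimming")
  expect_error(cohort_design(reg,
    behavior_link = list(region_ids = 9L, weights = 1)),
    "behavior_link region id")
  expect_error(cohort_design(reg, severity_sparing = list(mod = 1.5)),
               "sparing fractions")
  # unknown region id in the design against the atlas
  atl <- small_atlas(2)
  des <- cohort_design(data.frame(id = c(1, 7), mean_count = 5,
                                  dual_probability = 0.1))
  expect_error(simulate_cohort(des, atl), "region id not present")
})

test_that("sparing fraction 1 leaves counts unthinned", {
  atl <- small_atlas(2)
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = 100, dual_probability = 0.3),
    severity_sparing = list(sham = 1.0),
    arms = data.frame(condition = "sham", severity = "sham", n_animals = 4),
    seed = 3)
  co <- simulate_cohort(des, atl)
  expect_true(all(co$truth$n_lumbar_kept == co$truth$n_lumbar_true))
  expect_true(all(co$truth$realized_sparing == 1))
})

test_that("realized counts recover the design mean within Monte-Carlo error", {
  atl <- small_atlas(2)
  mu <- 200; size <- 40; n_an <- 40
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = mu, dual_probability = 0,
                         cervical_mean_count = 0),
    arms = data.frame(condition = "uninjured", severity = "none",
                      n_animals = n_an),
    dispersion = size, seed = 11)
  co <- simulate_cohort(des, atl)
  se <- sqrt((mu + mu^2 / size) / n_an)
  for (r in 1:2) {
    m <- mean(co$truth$n_lumbar_true[co$truth$region == r])
    expect_lt(abs(m - mu), 3 * se)
  }
})

test_that("counts are overdispersed for finite size and Poisson in the limit", {
  atl <- small_atlas(2)
  base <- function(size, seed) cohort_design(
    regions = data.frame(id = 1:2, mean_count = 100, dual_probability = 0,
                         cervical_mean_count = 0),
    dispersion = size,
    arms = data.frame(condition = "uninjured", severity = "none",
                      n_animals = 60),
    seed = seed)
  co_nb <- simulate_cohort(base(5, 21), atl)
  v <- co_nb$truth$n_lumbar_true[co_nb$truth$region == 1]
  expect_gt(var(v) / mean(v), 5)          # theory: 1 + mu/size = 21
  co_pois <- simulate_cohort(base(Inf, 22), atl)
  v <- co_pois$truth$n_lumbar_true[co_pois$truth$region == 1]
  expect_lt(var(v) / mean(v), 2)
  expect_gt(var(v) / mean(v), 0.5)
})

test_that("co-injected arms show the designed cross-channel correlation", {
  atl <- small_atlas(2)
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = 600, dual_probability = 0,
                         cervical_mean_count = 0),
    intensity_model = list(correlation = 0.6),
    arms = data.frame(condition = "coinjected", severity = "none",
                      n_animals = 2),
    coinjected_dual_probability = 0.658, seed = 17)
  co <- simulate_cohort(des, atl)
  lum <- co$animals[[1]]$lumbar
  cer <- co$animals[[1]]$cervical
  # dual cells appear in both channels with correlated log intensities
  shared <- intersect(lum$cell_id[lum$dual], cer$cell_id)
  ct <- cor.test(log(lum$intensity[match(shared, lum$cell_id)]),
                 log(cer$intensity[match(shared, cer$cell_id)]))
  expect_gt(ct$conf.int[1], 0)
  expect_true(ct$conf.int[1] <= 0.6 && ct$conf.int[2] >= 0.6)
  # and the co-detection fraction tracks the baseline probability
  p_hat <- mean(lum$dual)
  expect_lt(abs(p_hat - 0.658), 3 * sqrt(0.658 * 0.342 / nrow(lum)))
})

test_that("behavior scores track sparing of linked regions only", {
  atl <- small_atlas(2)
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = 120, dual_probability = 0,
                         cervical_mean_count = 0),
    severity_sparing = list(graded = stats::setNames(c(0.5, 0.5), 1:2)),
    behavior_link = list(region_ids = 1L, weights = 1, noise_sd = 0.3),
    arms = data.frame(condition = "graded", severity = "graded",
                      n_animals = 50),
    seed = 23)
  co <- simulate_cohort(des, atl)
  s1 <- co$truth$realized_sparing[co$truth$region == 1]
  s2 <- co$truth$realized_sparing[co$truth$region == 2]
  bms <- co$metadata$bms
  ct1 <- suppressWarnings(cor.test(bms, s1, method = "spearman",
                                   exact = FALSE))
  ct2 <- suppressWarnings(cor.test(bms, s2, method = "spearman",
                                   exact = FALSE))
  expect_gt(ct1$estimate, 0)
  expect_lt(ct1$p.value, 0.01)
  expect_gt(ct2$p.value, 0.05)   # unlinked region: consistent with zero
  expect_true(all(bms >= 0 & bms <= 9))
})

test_that("rendered stacks match the closed-form Gaussian integral", {
  # empty set: pure background
  st <- simulate_nuclei_stack(data.frame(x_um = numeric(0),
                                         y_um = numeric(0),
                                         z_um = numeric(0),
                                         intensity = numeric(0)),
                              shape = c(16, 16, 8), voxel_size_um = c(2, 2, 5),
                              background = 50, noise_sd = 0)
  expect_true(all(st$data == 50))
  # single blob: peak voxel at the rounded point location
  st1 <- simulate_nuclei_stack(data.frame(x_um = 17, y_um = 9, z_um = 22,
                                          intensity = 300),
                               shape = c(16, 16, 10),
                               voxel_size_um = c(2, 2, 5),
                               blob_sigma_um = c(1.7, 3.4),
                               background = 0, noise_sd = 0)
  pk <- arrayInd(which.max(st1$data), dim(st1$data))
  expect_equal(as.vector(pk), c(9, 5, 5))  # voxel containing (17, 9, 22)
  # integrated intensity: product of three 1D Gaussian integrals
  sig_vox <- c(1.7 / 2, 1.7 / 2, 3.4 / 5)
  analytic <- 300 * prod(sig_vox * sqrt(2 * pi))
  expect_equal(sum(st1$data), analytic, tolerance = 0.02)
  # out-of-bounds point is an error
  expect_error(simulate_nuclei_stack(data.frame(x_um = 1e4, y_um = 1,
                                                z_um = 1, intensity = 1),
                                     shape = c(16, 16, 8),
                                     voxel_size_um = 2),
               "outside the stack bounds")
})

test_that("lesion sections record their ground-truth bridge fraction", {
  expect_equal(simulate_gfap_section(100, 60,
                                     list(c(1, 100)))$truth_fraction, 1)
  expect_equal(simulate_gfap_section(100, 60, list())$truth_fraction, 0)
  expect_equal(simulate_gfap_section(100, 60,
                                     list(c(11, 40)))$truth_fraction, 0.30)
  expect_error(simulate_gfap_section(100, 60, list(c(10, 30), c(20, 50))),
               "overlap")
  expect_error(simulate_gfap_section(100, 60, list(c(90, 120))),
               "outside image width")
})
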