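test_that("the lumbar-projection index is the per-region channel fraction", {
  cts <- counts_df(animal_id = "a",
                   channel = rep(c("lumbar", "cervical"), each = 3),
                   region = rep(c("A", "B", "C"), 2),
                   count = c(30, 5, 0, 70, 0, 0))
  idx <- lumbar_projection_index(cts)
  pa <- idx$per_animal
  expect_equal(pa$value[pa$region == "A"], 0.30)
  expect_equal(pa$value[pa$region == "B"], 1.00)  # cervical zero
  expect_true(pa$undefined[pa$region == "C"])    # zero total
  expect_true(is.na(idx$per_region$mean[idx$per_region$region == "C"]))
  # brain-wide totals mode: 35 / 105
  expect_equal(idx$brainwide$mean, 35 / 105)
  # invariant to uniform scaling of both channels
  cts5 <- cts; cts5$count <- cts5$count * 5L
  expect_equal(lumbar_projection_index(cts5)$per_animal$value, pa$value)
  expect_error(lumbar_projection_index(cts[cts$channel == "lumbar", ]),
               "both 'lumbar' and 'cervical'")
})

test_that("the index averages per animal and recovers known ratios", {
  atl <- small_atlas(2, shape = c(40, 40, 40))
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = c(300, 100),
                         dual_probability = 0,
                         cervical_mean_count = c(700, 100)),
    arms = data.frame(condition = "uninjured", severity = "none",
                      n_animals = 12),
    seed = 43)
  co <- simulate_cohort(des, atl)
  cts <- count_by_region(assign_cohort(co, atl), atl$ontology, "leaf")
  idx <- lumbar_projection_index(cts)
  truth <- c(R1 = 0.3, R2 = 0.5)
  for (r in names(truth)) {
    row <- idx$per_region[idx$per_region$region == r, ]
    expect_lt(abs(row$mean - truth[[r]]), 3 * row$sem + 0.01)
  }
})

test_that("sparing is a percentage of the uninjured reference mean", {
  ref <- counts_df(animal_id = rep(c("u1", "u2"), each = 2),
                   channel = "lumbar", region = rep(c("A", "B"), 2),
                   count = c(100, 50, 140, 70))
  inj <- counts_df(animal_id = "i1", channel = "lumbar",
                   region = c("A", "B"), count = c(120, 0))
  sp <- sparing_index(inj, ref, exclude = character(0))
  pa <- sp$per_animal
  expect_equal(pa$sparing_pct[pa$region == "A"], 100)  # equals ref mean 120
  expect_equal(pa$sparing_pct[pa$region == "B"], 0)
  expect_equal(sp$brainwide$sparing_pct, 100 * 120 / 180)
  # zero reference mean is flagged excluded
  ref0 <- rbind(ref, counts_df(animal_id = c("u1", "u2"), channel = "lumbar",
                               region = "Z", count = c(0, 0)))
  inj0 <- rbind(inj, counts_df(animal_id = "i1", channel = "lumbar",
                               region = "Z", count = 3))
  sp0 <- sparing_index(inj0, ref0, exclude = character(0))
  expect_true(sp0$per_animal$excluded[sp0$per_animal$region == "Z"])
  # the exclusion list drops the region from brain-wide values
  spx <- sparing_index(inj, ref, exclude = "B")
  expect_equal(spx$brainwide$sparing_pct, 100 * 120 / 120)
  expect_error(sparing_index(inj, inj), "at least 2 animals")
})

test_that("sparing averages 100% when injured counts come from the reference law", {
  atl <- small_atlas(2)
  des <- cohort_design(
    regions = data.frame(id = 1:2, mean_count = 150, dual_probability = 0,
                         cervical_mean_count = 0),
    severity_sparing = list(sham = 1.0),
    arms = data.frame(condition = c("uninjured", "sham"),
                      severity = c("none", "sham"), n_animals = c(20, 20)),
    seed = 47)
  co <- simulate_cohort(des, atl)
  cts <- count_by_region(assign_cohort(co, atl), atl$ontology, "leaf")
  cts <- cts[cts$channel == "lumbar", ]
  sp <- sparing_index(cts[grepl("^sham", cts$animal_id), ],
                      cts[grepl("^uninjured", cts$animal_id), ],
                      exclude = character(0))
  for (r in unique(sp$per_region$region)) {
    row <- sp$per_region[sp$per_region$region == r, ]
    expect_lt(abs(row$mean_sparing_pct - 100), 3.5 * row$sem + 2)
  }
})

test_that("brain-wide summaries match an independent recount", {
  one <- counts_df(animal_id = "a", channel = "lumbar",
                   region = c("A", "B", "C"), count = c(1, 0, 2))
  s <- brainwide_summary(one)
  expect_equal(s$per_animal$total, 3L)
  expect_equal(s$n_detected_regions, 2L)
  two <- rbind(one, transform(one, animal_id = "b"))
  s2 <- brainwide_summary(two)
  expect_equal(s2$total$sem, 0)
  expect_equal(s2$total$mean, 3)
  # random table: summaries equal direct tapply recomputation
  set.seed(51)
  big <- counts_df(animal_id = rep(sprintf("a%d", 1:6), each = 8),
                   channel = "lumbar",
                   region = rep(sprintf("r%d", 1:8), 6),
                   count = rpois(48, 40))
  sb <- brainwide_summary(big)
  tot <- tapply(big$count, big$animal_id, sum)
  expect_equal(sb$per_animal$total[order(sb$per_animal$animal_id)],
               as.integer(tot[order(names(tot))]), ignore_attr = TRUE)
  expect_equal(sb$total$mean, mean(tot))
  expect_equal(sb$total$sem, sd(tot) / sqrt(6))
  pr_mean <- tapply(big$count, big$region, mean)
  expect_equal(sb$per_region$mean[order(sb$per_region$region)],
               as.vector(pr_mean[order(names(pr_mean))]))
})

test_that("bridge fraction measures GFAP continuity across the lesion", {
  # uniform GFAP-positive band: full continuity
  full <- simulate_gfap_section(100, 60, list(c(1, 100)))
  expect_equal(bridge_fraction(full)$fraction_pct, 100)
  # full-width negative gap: zero
  gap <- simulate_gfap_section(100, 60, list())
  expect_equal(bridge_fraction(gap)$fraction_pct, 0)
  # 30% spans recovered within one column of quantization
  g <- simulate_gfap_section(100, 60, list(c(11, 25), c(60, 74)))
  bf <- bridge_fraction(g)
  expect_lt(abs(bf$fraction_pct - 100 * g$truth_fraction), 1 + 1e-9)
  # invariant to intensity rescaling on either side of the threshold
  g2 <- g; g2$image <- g2$image * 1000
  expect_equal(bridge_fraction(g2, gfap_threshold = 500)$fraction_pct,
               bf$fraction_pct)
  # a diagonal path counts through 8-connectivity
  img <- matrix(0, 5, 5)
  for (k in 1:5) img[k, k] <- 1
  bf_diag <- bridge_fraction(img, lesion_band = c(1, 5))
  expect_equal(bf_diag$n_bridge_columns, 5L)
  expect_error(bridge_fraction(img, lesion_band = c(1, 9)), "outside")
  expect_error(bridge_fraction(img, lesion_band = c(1, 5),
                               cord_columns = integer(0)), "empty cord")
})
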