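test_that("array designs have the forced counts and are seed-deterministic", {
  d <- make_array_design(1, 10, 2, 3, seed = 7)
  expect_equal(nrow(d$clones), 10)
  expect_equal(d$replicates, 3L)
  expect_equal(length(unique(d$clones$clone_id)), 10)
  d2 <- make_array_design(1, 10, 2, 3, seed = 7)
  expect_identical(d, d2)

  big <- make_array_design(18, 200, 72, 3, seed = 1)
  expect_equal(nrow(big$clones), 3600)
  expect_equal(length(unique(big$clones$block)), 72)
  # genome-ordered, non-overlapping tiling within each region
  for (r in unique(big$clones$region_label)) {
    cl <- big$clones[big$clones$region_label == r, ]
    expect_true(all(diff(cl$start) > 0))
    expect_true(all(cl$start[-1] > cl$end[-nrow(cl)]))
    expect_true(all(cl$start <= cl$end))
  }
  expect_error(make_array_design(0, 10, 2, 3), "positive")
})

test_that("planted truth matches the requested prevalence structure", {
  d <- tiny_design()
  labels <- unique(d$clones$region_label)
  # degenerate prevalence 1: every sample carries the gain on every clone
  tr <- simulate_truth(d, cohort_spec(5, regions = setNames(
    list(list(direction = "gain", prevalence = 1)), labels[1]), seed = 3))
  in_region <- d$clones$region_label == labels[1]
  for (p in tr$profiles) {
    expect_true(all(p$states[d$clones$clone_id[in_region]] == 1L))
    expect_true(all(p$states[d$clones$clone_id[!in_region]] == 0L))
  }
  # prevalence 0 everywhere: all states neutral
  tr0 <- simulate_truth(d, cohort_spec(5, seed = 3))
  expect_true(all(vapply(tr0$profiles, function(p) all(p$states == 0L), logical(1))))
  # prevalence 0.6 at n = 500: within the binomial concentration bound
  tr6 <- simulate_truth(d, cohort_spec(500, regions = setNames(
    list(list(direction = "loss", prevalence = 0.6)), labels[2]), seed = 9))
  clone1 <- d$clones$clone_id[d$clones$region_label == labels[2]][1]
  frac <- mean(vapply(tr6$profiles, function(p) p$states[clone1] == -1L, logical(1)))
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 500))
  expect_error(simulate_truth(d, cohort_spec(5, regions = list(
    NOPE = list(direction = "gain", prevalence = 0.5)))), "unknown region")
})

test_that("noise-free hybridization reproduces the state-shift model exactly", {
  d <- tiny_design(n_regions = 1, clones_per_region = 5)
  zero <- structure(list(sample_id = "t", purity = 1,
                         states = setNames(rep(0L, 5), d$clones$clone_id)),
                    class = "truth_profile")
  s0 <- simulate_hybridization(d, zero, noise_sd = 0, seed = 1)
  expect_true(all(s0$log2ratio == 0))
  one <- zero
  one$states[1] <- 1L
  s1 <- simulate_hybridization(d, one, noise_sd = 0, seed = 1)
  expect_equal(unique(s1$log2ratio[s1$clone_id == d$clones$clone_id[1]]),
               log2(1.5))
  # purity attenuation: p = 0.5 gain -> log2(1.25)
  half <- one
  half$purity <- 0.5
  sh <- simulate_hybridization(d, half, noise_sd = 0, seed = 1)
  expect_equal(unique(sh$log2ratio[sh$clone_id == d$clones$clone_id[1]]),
               log2(1.25))
  # loss at purity 1 -> log2(1/2)
  lost <- zero
  lost$states[2] <- -1L
  sl <- simulate_hybridization(d, lost, noise_sd = 0, seed = 1)
  expect_equal(unique(sl$log2ratio[sl$clone_id == d$clones$clone_id[2]]),
               log2(0.5))
})

test_that("replicate spread tracks the requested noise SD", {
  d <- tiny_design(n_regions = 2, clones_per_region = 100, n_blocks = 1)
  ss <- simulate_selfself(d, noise_sd = 0.2, seed = 13)
  reps <- split(ss$log2ratio, ss$clone_id)
  sds <- vapply(reps, sd, numeric(1))
  # RMS of per-clone replicate SDs is unbiased for the spot noise scale
  # (the plain mean of n = 3 SDs is biased low by the c4 factor)
  expect_equal(sqrt(mean(sds^2)), 0.2, tolerance = 0.03)
  expect_identical(ss, simulate_selfself(d, noise_sd = 0.2, seed = 13))
})

test_that("expression generator honors the concordance probability", {
  states <- setNames(rep(c(1L, -1L), 10), sprintf("G%02d", 1:20))
  ex1 <- simulate_expression(states, concordance_prob = 1, seed = 2)
  expect_true(all(ex1$ratio[ex1$state == 1] > 1))
  expect_true(all(ex1$ratio[ex1$state == -1] < 1))
  big <- setNames(rep(1L, 1000), sprintf("H%04d", 1:1000))
  exh <- simulate_expression(big, concordance_prob = 0.5, seed = 8)
  frac <- mean(exh$ratio > 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("validation generator applies delta-Ct arithmetic and is deterministic", {
  amp <- setNames(c(TRUE, FALSE), c("a", "b"))
  v <- simulate_validation(amp, dosage = 2, seed = 4)
  tum <- v$ct[v$ct$tissue == "tumor", ]
  expect_equal(tum$ct_target[tum$sample_id == "a"],
               tum$ct_reference[tum$sample_id == "a"] - 1)
  expect_equal(tum$ct_target[tum$sample_id == "b"],
               tum$ct_reference[tum$sample_id == "b"])
  # zero-noise CISH fractions sit at the baseline/amplified parameters
  expect_equal(v$cish$n_nuclei_ge4[v$cish$sample_id == "b"], 10L)
  expect_equal(v$cish$n_nuclei_ge4[v$cish$sample_id == "a"], 60L)
  expect_identical(v, simulate_validation(amp, dosage = 2, seed = 4))
})
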