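test_that("a constant noise-free profile yields one segment and no breakpoints", {
  seg <- segment_profile(vec_profile(rep(0.5, 20)))
  expect_equal(nrow(seg$breakpoints), 0)
  expect_equal(length(unique(seg$clones$segment)), 1)
  # NIG posterior mean of the single segment shrinks 0.5 only by k0/(k0+n)
  expect_equal(unique(seg$clones$segment_mean), 0.5 * 20 / 20.01, tolerance = 1e-12)
  # the exact posterior mean varies minutely along the sequence (ends sit
  # in shorter segments on average, so shrinkage differs); it stays flat
  # to well under the calling scale
  expect_lt(diff(range(seg$clones$posterior_mean)), 1e-4)
})

test_that("dynamic program equals the enumeration oracle on short profiles", {
  set.seed(101)
  for (k in 1:40) {
    n <- sample(1:10, 1)
    y <- rnorm(n, sample(c(0, 1.5), 1), 0.5)
    p_c <- sample(c(0.01, 0.1, 0.4), 1)
    prior <- nig_prior(k0 = sample(c(0.01, 1), 1))
    seg <- segment_profile(vec_profile(y), p_c = p_c, prior = prior)
    ora <- enumerate_posterior_oracle(y, p_c = p_c, prior = prior)
    expect_equal(seg$clones$posterior_mean, ora$post_mean, tolerance = 1e-8)
    if (n > 1) {
      expect_equal(seg$clones$cp_prob_after[seq_len(n - 1)], ora$cp_prob,
                   tolerance = 1e-8)
    }
    expect_equal(unname(seg$log_evidence), ora$log_evidence, tolerance = 1e-8)
  }
})

test_that("oracle closed forms hold at n = 1 and n = 2", {
  # single observation: NIG-shrunken value
  ora <- enumerate_posterior_oracle(2, p_c = 0.01, prior = nig_prior(k0 = 0.01))
  expect_equal(ora$post_mean, 1.9801980198, tolerance = 1e-9)
  # two identical values: the data support a joint segment, so the
  # changepoint posterior falls below its prior
  ora2 <- enumerate_posterior_oracle(c(0.3, 0.3), p_c = 0.2)
  expect_lt(ora2$cp_prob, 0.2)
  expect_error(enumerate_posterior_oracle(rnorm(15)), "n <= 14")
})

test_that("posterior means are shift-equivariant in the flat-mean-prior limit", {
  set.seed(55)
  y <- rnorm(30, 0, 0.3) + rep(c(0, 1), each = 15)
  flat <- nig_prior(k0 = 1e-8)
  a <- segment_profile(vec_profile(y), prior = flat)$clones$posterior_mean
  b <- segment_profile(vec_profile(y + 2.5), prior = flat)$clones$posterior_mean
  expect_equal(b - a, rep(2.5, 30), tolerance = 1e-5)
})

test_that("a planted step is located at the true gap", {
  set.seed(77)
  y <- c(rnorm(50, 0, 0.2), rnorm(50, 1.5, 0.2))
  seg <- segment_profile(vec_profile(y))
  expect_equal(seg$breakpoints$after_clone_id, "c050")
  expect_equal(length(unique(seg$clones$segment)), 2)
})

test_that("missing clones are skipped, never interpolated", {
  y <- c(0.5, NA, 0.5, 0.5, NA, 0.5)
  seg <- segment_profile(vec_profile(y))
  expect_true(all(is.na(seg$clones$posterior_mean[c(2, 5)])))
  expect_equal(sum(!is.na(seg$clones$posterior_mean)), 4)
  calls <- call_states(seg, tau = 0.3)
  expect_true(all(is.na(calls$state[c(2, 5)])))
  expect_true(all(calls$state[c(1, 3, 4, 6)] == 1L))
  all_na <- vec_profile(c(NA, NA))
  expect_error(segment_profile(all_na), "no observed clones")
})

test_that("state calling applies the ternary threshold rule", {
  seg <- segment_profile(vec_profile(rep(c(0.9, -0.9, 0.1), each = 15)))
  calls <- call_states(seg, tau = 0.3)
  expect_equal(unique(calls$state[1:15]), 1L)
  expect_equal(unique(calls$state[16:30]), -1L)
  expect_equal(unique(calls$state[31:45]), 0L)
  expect_error(call_states(seg, tau = 0), "positive")
})

test_that("default tau scales the self-self spread", {
  set.seed(3)
  v <- rnorm(4000, 0, 0.2)
  expect_equal(default_tau(v), 0.6, tolerance = 0.03)
  expect_equal(default_tau(v, multiplier = 2), 2 * sd(v))
})
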