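test_that("shipped models load with the published sizes", {
  expect_equal(build_model("human_constant")$N_A, 10000)
  expect_equal(build_model("dmel_constant")$N_A, 1720600)
  expect_equal(build_model("athal_constant")$N_A, 10000)
  expect_equal(build_model("athal_3epoch_SMA")$epochs$size_start,
               c(161744, 24076, 203077))
  expect_error(build_model("neanderthal"), "human_constant")
  for (nm in sweepconv:::MODEL_NAMES) {
    m <- build_model(nm)
    expect_s3_class(m, "demographic_model")
    expect_true(is.na(m$epochs$duration[1]))
    expect_identical(m$epochs$growth_rate[1], 0)
    expect_equal(m$N_A, round(m$epochs$size_start[1]))
    expect_equal(m$Q, 1L)
    if (nrow(m$epochs) > 1)
      expect_true(all(m$epochs$duration[-1] >= 1))
  }
})

test_that("model JSON round-trips through write_model/read_model", {
  m <- build_model("human_EUR_tennessen")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$epochs, m$epochs)
  expect_equal(m2$c, m$c)
})

test_that("rescale_model divides sizes and durations, records Q", {
  h10 <- rescale_model(build_model("human_constant"), 10)
  expect_equal(h10$N_A, 1000)
  expect_equal(h10$Q, 10L)
  expect_equal(h10$N_A_unscaled, 10000)
  expect_equal(rescale_model(build_model("dmel_constant"), 100)$N_A, 17206)
  m <- build_model("athal_3epoch_SMA")
  expect_identical(rescale_model(m, 1), m)
  expect_error(rescale_model(h10, 10), "already rescaled")
  expect_error(rescale_model(m, 0), "positive integer")
  expect_error(rescale_model(m, 2.5), "positive integer")
  m10 <- rescale_model(m, 10)
  expect_equal(m10$epochs$size_start, round(m$epochs$size_start / 10))
  expect_equal(m10$epochs$duration[-1], round(m$epochs$duration[-1] / 10))
})

test_that("size_at evaluates piecewise histories", {
  hc <- build_model("human_constant")
  expect_equal(size_at(hc, c(0, 1, 5e6)), rep(10000L, 3))
  expect_equal(size_at(rescale_model(hc, 10), c(0, 7, 1e5)), rep(1000L, 3))
  at <- build_model("athal_3epoch_SMA")
  expect_equal(size_at(at, 30000), 161744L)   # inside oldest epoch
  expect_equal(size_at(at, 20000), 24076L)    # bottleneck epoch
  expect_equal(size_at(at, 0), 203077L)
  expect_error(size_at(at, -1), "non-negative")
  ## deterministic
  eur <- build_model("human_EUR_tennessen")
  expect_identical(size_at(eur, 0:1000), size_at(eur, 0:1000))
  ## growth epochs: EUR present-day size near the catalog value 501436
  expect_lt(abs(size_at(eur, 0) / 501436 - 1), 0.01)
  ## monotone growth within the most recent EUR epoch
  recent <- size_at(eur, 0:200)
  expect_true(all(diff(recent) <= 0))  # sizes shrink going back in time
})

test_that("rescaled size_at tracks unscaled size_at / Q", {
  for (nm in c("human_constant", "athal_3epoch_SMA", "human_EUR_tennessen",
               "dmel_3epoch_sheehan")) {
    m <- build_model(nm)
    Q <- m$default_Q
    ms <- rescale_model(m, Q)
    ## interior probe points away from epoch boundaries (> 2 scaled gens)
    edges <- ms$epochs$start_bp[is.finite(ms$epochs$start_bp)]
    probes <- unique(pmax(0, c(0, 5, 50, round(edges / 2), edges + 5,
                               max(c(edges, 10)) * 2)))
    probes <- probes[vapply(probes, function(t)
      all(abs(t - edges) > 2), logical(1))]
    expect_gt(length(probes), 2)
    scaled <- size_at(ms, probes)
    unscaled <- size_at(m, probes * Q)
    ## epoch of each probe in the scaled model, to set the tolerance:
    ## rounding durations to integers can shift a boundary by Q/2
    ## unscaled generations, so steep growth epochs drift by up to
    ## exp(r_scaled / 2) in size
    K <- nrow(ms$epochs)
    idx <- rep.int(K, length(probes))
    if (K > 1) for (k in rev(seq_len(K - 1)))
      idx[probes >= ms$epochs$start_bp[k + 1]] <- k
    tol <- 0.02 + exp(abs(ms$epochs$growth_rate[idx]) / 2) - 1
    expect_true(all(abs(scaled - unscaled / Q) <=
                      pmax(1, tol * unscaled / Q)),
                label = paste("rescaling consistency for", nm))
  }
})

test_that("onset_generation uses the unscaled ancestral size", {
  hc <- build_model("human_constant")
  expect_equal(onset_generation(hc, 1), 40000L)
  expect_equal(onset_generation(rescale_model(hc, 10), 0.05), 200L)
  expect_equal(onset_generation(rescale_model(build_model("dmel_constant"),
                                              100), 1), 68824L)
  expect_error(onset_generation(hc, 0), "positive")
  expect_error(onset_generation(hc, -0.5), "positive")
})

test_that("Sheehan-Song bottleneck spans the published onset window", {
  m <- build_model("dmel_3epoch_sheehan")
  four_NA <- 4 * m$N_A
  edges <- m$epochs$start_bp[is.finite(m$epochs$start_bp)]
  ## bottleneck runs from ~0.84 x 4N_A to ~0.077 x 4N_A generations ago
  ## (published to two significant figures)
  expect_equal(max(edges) / four_NA, 0.84, tolerance = 0.01)
  expect_equal(min(edges) / four_NA, 0.077, tolerance = 0.01)
})

test_that("conversion_probability reproduces the species baselines", {
  ## printed baseline composite rates: 6.55e-6, 8.98e-6, 4.03e-7
  expect_equal(conversion_probability(1.30981e-8, 1, 1), 6.55e-6,
               tolerance = 1e-3)
  expect_equal(conversion_probability(1.7966e-8, 1, 1), 8.98e-6,
               tolerance = 1e-3)
  expect_equal(conversion_probability(8.06452e-10, 1, 1), 4.03e-7,
               tolerance = 1e-3)
  ## model files carry the same c values
  expect_equal(build_model("human_constant")$c, 1.30981e-8)
  expect_equal(build_model("dmel_constant")$c, 1.7966e-8)
  expect_equal(build_model("athal_constant")$c, 8.06452e-10)
})

test_that("conversion_probability is linear in g and Q and guarded", {
  c0 <- 1.3e-8
  expect_equal(conversion_probability(c0, 10, 1),
               10 * conversion_probability(c0, 1, 1))
  expect_equal(conversion_probability(c0, 1, 100),
               100 * conversion_probability(c0, 1, 1))
  expect_identical(conversion_probability(c0, 0, 5), 0)
  expect_error(conversion_probability(1e-3, 50, 100), ">= 1")
  expect_error(conversion_probability(-1e-8, 1, 1), "positive")
  expect_error(conversion_probability(c0, 1, 0.5), "Q")
})

test_that("demographic_model validates epoch structure", {
  expect_error(demographic_model("x", list(
    list(duration = 5, size_start = 100, growth_rate = 0))), "unbounded")
  expect_error(demographic_model("x", list(
    list(duration = NA, size_start = 100, growth_rate = 0.1))),
    "growth rate 0")
  expect_error(demographic_model("x", list(
    list(duration = NA, size_start = 1, growth_rate = 0))), ">= 2")
  expect_error(demographic_model("x", list(
    list(duration = NA, size_start = 100, growth_rate = 0),
    list(duration = 0.2, size_start = 50, growth_rate = 0))), ">= 1")
})
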