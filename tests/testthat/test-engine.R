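test_that("sweep_params scales selection by Q and validates inputs", {
  p <- sweep_params(0.01, 0.5, t_s = 0.05, g = 1, Q = 10)
  expect_equal(p$s_prime, 0.1)
  expect_equal(p$Q, 10L)
  expect_error(sweep_params(-0.01, 0.5, 1), "s")
  expect_error(sweep_params(0.01, 2, 1), "h")
  expect_error(sweep_params(0.01, 0.5, 0), "t_s")
})

test_that("gamete_distribution handles segregation and conversion", {
  ## Mendelian segregation, no conversion
  expect_equal(gamete_distribution("AB", "ab", 0),
               c(AB = 0.5, aB = 0, Ab = 0, ab = 0.5))
  ## conversion splits probability across the four products:
  ## template AB -> AB (0.45) or Ab (0.05); template ab -> ab or aB
  expect_equal(gamete_distribution("AB", "ab", 0.1),
               c(AB = 0.45, aB = 0.05, Ab = 0.05, ab = 0.45))
  ## homozygote: conversion silent
  expect_equal(gamete_distribution("AB", "AB", 0.5), c(AB = 1, aB = 0,
                                                       Ab = 0, ab = 0))
  ## both carry B: conversion at the B locus changes nothing
  expect_equal(gamete_distribution("AB", "aB", 0.2),
               c(AB = 0.5, aB = 0.5, Ab = 0, ab = 0))
  expect_error(gamete_distribution("AB", "xy", 0.1), "unknown haplotype")
})

test_that("gamete_distribution sums to one and is symmetric", {
  set.seed(42)
  haps <- c("AB", "aB", "Ab", "ab")
  for (i in 1:20) {
    h1 <- sample(haps, 1); h2 <- sample(haps, 1)
    G <- runif(1, 0, 0.9)
    d12 <- gamete_distribution(h1, h2, G)
    expect_equal(sum(d12), 1)
    expect_equal(d12, gamete_distribution(h2, h1, G))
    ## the A-locus marginal is untouched by conversion
    expect_equal(d12[["AB"]] + d12[["Ab"]],
                 mean(c(h1, h2) %in% c("AB", "Ab")))
  }
})

test_that("offspring_distribution matches hand-computed two-genotype case", {
  ## weights 1 (ab/ab) and 1.5 (AB/ab) -> parent probs 0.4/0.6;
  ## P(gamete AB) = 0.6 * 0.5 = 0.3; P(offspring AB/AB) = 0.09
  p <- offspring_distribution(c("ab/ab" = 1, "AB/ab" = 1),
                              s_prime = 1, h = 0.5, G = 0)
  expect_equal(p[["AB/AB"]], 0.09)
  expect_equal(p[["AB/ab"]], 2 * 0.3 * 0.7)
  expect_equal(p[["ab/ab"]], 0.49)
  expect_equal(sum(p), 1)
})

test_that("offspring_distribution edge behaviors", {
  ## monomorphic population reproduces itself
  p <- offspring_distribution(c("ab/ab" = 1), s_prime = 2, h = 1, G = 0.3)
  expect_equal(p[["ab/ab"]], 1)
  ## neutral case equals random union of unweighted gametes
  set.seed(7)
  for (i in 1:10) {
    counts <- random_genotype_state(30L)
    G <- runif(1, 0, 0.5)
    p0 <- offspring_distribution(counts, s_prime = 0, h = 0.7, G = G)
    ## build the unweighted gamete marginal by brute force
    q <- numeric(4)
    for (gt in which(counts > 0)) {
      pair <- strsplit(names(counts)[gt], "/")[[1]]
      q <- q + counts[gt] * gamete_distribution(pair[1], pair[2], G)
    }
    q <- q / sum(counts)
    expected <- q[sweepconv:::GENOTYPE_I] * q[sweepconv:::GENOTYPE_J] *
      ifelse(sweepconv:::GENOTYPE_I == sweepconv:::GENOTYPE_J, 1, 2)
    expect_equal(unname(p0), unname(expected))
    expect_equal(sum(p0), 1)
  }
  expect_error(offspring_distribution(genotype_counts(), 0.1, 0.5, 0),
               "at least one individual")
})

test_that("C++ offspring probabilities agree with the R reference", {
  set.seed(11)
  for (i in 1:40) {
    counts <- random_genotype_state(80L)
    s <- runif(1, 0, 2); h <- runif(1); G <- runif(1, 0, 0.8)
    expect_equal(as.numeric(sweepconv:::cpp_offspring_probs(counts, s, h, G)),
                 unname(offspring_distribution(counts, s, h, G)),
                 tolerance = 1e-12)
  }
})

test_that("wf_step conserves counts, is seed-deterministic, and matches
           its target distribution", {
  counts <- genotype_counts()
  counts[c("AB/ab", "aB/ab", "ab/ab")] <- c(5, 2, 13)
  set.seed(1)
  nxt <- wf_step(counts, s_prime = 0.3, h = 0.5, G = 0.1, N_next = 57)
  expect_equal(sum(nxt), 57)
  set.seed(99); a <- wf_step(counts, 0.3, 0.5, 0.1, 100)
  set.seed(99); b <- wf_step(counts, 0.3, 0.5, 0.1, 100)
  expect_identical(a, b)
  ## goodness of fit: one multinomial draw of 1e5 offspring is 1e5 iid
  ## draws from offspring_distribution
  p <- offspring_distribution(counts, 0.3, 0.5, 0.1)
  set.seed(2)
  obs <- wf_step(counts, 0.3, 0.5, 0.1, N_next = 1e5)
  keep <- p > 0
  chi2 <- sum((obs[keep] - 1e5 * p[keep])^2 / (1e5 * p[keep]))
  expect_gt(pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE), 0.001)
  expect_true(all(obs[!keep] == 0))
})

test_that("run_replicate conserves chromosomes and conditions on non-loss", {
  m <- toy_constant_model(100)
  p <- sweep_params(0.2, 0.5, t_s = 0.5, g = 2)  # G = 0.02
  for (sd in 1:25) {
    r <- run_replicate(m, p, seed = sd)
    expect_equal(sum(r$pop_counts), 2 * r$N_final)
    expect_gte(r$pop_counts[["AB"]] + r$pop_counts[["aB"]], 1)
    expect_equal(sum(r$sample_counts), min(200, 2 * r$N_final))
    expect_true(all(r$sample_counts <= r$pop_counts))
    if (r$fixed) {
      expect_equal(r$p_f, 1)
      expect_equal(r$pop_counts[["Ab"]] + r$pop_counts[["ab"]], 0)
    } else {
      expect_equal(r$p_f,
                   (r$pop_counts[["AB"]] + r$pop_counts[["aB"]]) /
                     (2 * r$N_final))
    }
  }
})

test_that("without conversion no aB haplotype can ever arise", {
  m <- toy_constant_model(100)
  p <- sweep_params(0.5, 0.5, t_s = 0.5, g = 0)
  for (sd in 1:30) {
    r <- run_replicate(m, p, seed = sd)
    expect_equal(r$pop_counts[["aB"]], 0)
    expect_equal(r$sample_counts[["aB"]], 0)
  }
})

test_that("run_replicate is reproducible and validates its inputs", {
  m <- toy_constant_model(60)
  p <- sweep_params(0.3, 1, t_s = 1, g = 1)
  r1 <- run_replicate(m, p, seed = 123)
  r2 <- run_replicate(m, p, seed = 123)
  expect_identical(r1$pop_counts, r2$pop_counts)
  expect_identical(r1$sample_counts, r2$sample_counts)
  expect_identical(r1$gens_elapsed, r2$gens_elapsed)
  ## sample shortfall when 2N < sample_n
  expect_equal(sum(run_replicate(m, p, seed = 1)$sample_counts), 120)
  ## Q mismatch between model and params
  expect_error(run_replicate(m, sweep_params(0.3, 1, 1, Q = 10), seed = 1),
               "rescale")
  ## restart cap trips for an impossible scenario
  expect_error(run_replicate(toy_constant_model(100),
                             sweep_params(0, 0, t_s = 0.5, g = 0),
                             seed = 1, restart_cap = 5),
               "restart cap")
})

test_that("trajectory recording matches the returned attempt", {
  m <- toy_constant_model(100)
  p <- sweep_params(0.4, 0.5, t_s = 0.5, g = 2)
  r <- run_replicate(m, p, seed = 17, trajectory = TRUE)
  tr <- r$trajectory
  expect_equal(nrow(tr), r$gens_elapsed + 1)
  expect_true(all(rowSums(tr) == 200))
  ## the attempt starts from a single AB copy among ab chromosomes
  expect_equal(unname(tr[1, ]), c(1, 0, 0, 199))
  ## final row agrees with the reported population counts
  expect_equal(unname(tr[nrow(tr), ]), unname(r$pop_counts))
  ## B count never hits zero in a conditioned replicate's returned attempt
  expect_true(all(tr[, "AB"] + tr[, "aB"] >= 1))
  ## CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(r, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$generation[1], r$onset_generation)
  expect_equal(back$aB, unname(tr[, "aB"]))
  expect_error(write_trajectory(run_replicate(m, p, seed = 1), path),
               "no recorded trajectory")
})
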