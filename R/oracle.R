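## Independent validation oracle: a brute-force individual-based
## re-implementation of the same two-locus model, plus diffusion-theory
## fixation-probability checks.  Intended for small N only; its purpose is
## to certify the genotype-count engine, never to replace it.

#' Individual-based sweep replicate (validation oracle)
#'
#' Simulates the same model as [run_replicate()] but at the level of
#' explicit individuals: each offspring draws two parents with probability
#' proportional to fitness (independently, so selfing is possible), takes
#' one gamete from each parent with an explicit per-gamete conversion
#' Bernoulli, and the loss/restart, termination and sampling rules are
#' identical to the engine's.  Orders of magnitude slower than the
#' genotype-count engine; use N of a few hundred at most.
#'
#' @inheritParams run_replicate
#' @return A `replicate_result` (same shape as [run_replicate()]).
#' @export
individual_based_replicate <- function(model, params, seed = NULL,
                                       sample_n = 200L, condition = TRUE,
                                       restart_cap = 1e7, G = NULL) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(params, "sweep_params"))
  if (model$Q != params$Q)
    stop("model rescaling (Q = ", model$Q, ") does not match params (Q = ",
         params$Q, ")")
  if (is.null(G)) {
    if (is.na(model$c))
      stop("model '", model$name, "' has no crossover rate c; pass G directly")
    G <- if (params$g == 0) 0 else
      conversion_probability(model$c, params$g, params$Q)
  }
  s_prime <- params$s_prime
  h <- params$h
  T_onset <- onset_generation(model, params$t_s)
  if (T_onset < 1L) stop("sweep onset rounds to the present")
  sizes <- size_at(model, seq.int(T_onset, 0L))
  if (!is.null(seed)) set.seed(seed)
  w_by_nB <- c(1, 1 + h * s_prime, 1 + s_prime)

  init_pop <- function(N) {
    ## haplotype codes 0..3; columns = individuals, rows = the two haplotypes
    pop <- matrix(3L, nrow = 2L, ncol = N)   # all ab/ab
    pop[1L, 1L] <- 0L                        # one AB/ab heterozygote
    pop
  }
  N0 <- sizes[1L]
  pop <- init_pop(N0)
  restarts <- 0
  fixed <- FALSE
  lost <- FALSE
  k <- 0L
  T <- length(sizes) - 1L
  while (k < T) {
    N <- ncol(pop)
    N_next <- sizes[k + 2L]
    w <- w_by_nB[hap_carries_B(pop[1L, ]) + hap_carries_B(pop[2L, ]) + 1L]
    parents <- sample.int(N, 2L * N_next, replace = TRUE, prob = w)
    tmpl <- sample.int(2L, 2L * N_next, replace = TRUE)
    t_hap <- pop[cbind(tmpl, parents)]
    o_hap <- pop[cbind(3L - tmpl, parents)]
    conv <- runif(2L * N_next) < G
    b_allele <- ifelse(conv, hap_carries_B(o_hap), hap_carries_B(t_hap))
    gam <- ifelse(b_allele, 0L, 2L) + ifelse(hap_carries_A(t_hap), 0L, 1L)
    pop <- matrix(gam, nrow = 2L)
    k <- k + 1L
    b <- sum(hap_carries_B(pop))
    if (b == 0L) {
      if (!condition) { lost <- TRUE; break }
      restarts <- restarts + 1
      if (restarts > restart_cap)
        stop("restart cap exceeded in individual-based oracle")
      pop <- init_pop(N0)
      k <- 0L
      next
    }
    if (b == 2L * N_next) { fixed <- TRUE; break }
  }
  haps <- as.integer(pop)
  hap_counts <- structure(as.numeric(tabulate(haps + 1L, nbins = 4L)),
                          names = HAPLOTYPES)
  two_n <- sum(hap_counts)
  n_take <- min(sample_n, two_n)
  samp <- structure(as.numeric(tabulate(sample(haps + 1L, n_take),
                                        nbins = 4L)), names = HAPLOTYPES)
  structure(list(fixed = fixed, lost = lost, gens_elapsed = k,
                 restarts = restarts, N_final = ncol(pop),
                 pop_counts = hap_counts, sample_counts = samp,
                 sample_n = n_take,
                 p_f = (hap_counts[["AB"]] + hap_counts[["aB"]]) / two_n,
                 params = params, model_name = model$name),
            class = "replicate_result")
}

#' Diffusion-approximation fixation probability
#'
#' Kimura's fixation probability of a single new copy (initial frequency
#' `1/(2N)`) under genotype fitnesses 1, 1 + h*s', 1 + s':
#' `u = int_0^{1/2N} psi(x) dx / int_0^1 psi(x) dx` with
#' `psi(x) = exp(-2*N*s'*(2*h*x + (1-2*h)*x^2))`.  For the additive case
#' (h = 0.5) this reduces to the closed form
#' `u = (1 - exp(-s')) / (1 - exp(-2*N*s'))`; for other dominance values
#' the integrals are evaluated numerically.
#'
#' @param N Constant diploid population size.
#' @param s_prime Scaled selection coefficient (0 allowed: neutral limit
#'   `1/(2N)`).
#' @param h Dominance coefficient.
#' @return Fixation probability.
#' @export
kimura_fixation_probability <- function(N, s_prime, h = 0.5) {
  stopifnot(N >= 2)
  if (s_prime == 0) return(1 / (2 * N))
  if (h == 0.5)
    return((1 - exp(-s_prime)) / (1 - exp(-2 * N * s_prime)))
  ## psi normalized by its value at 0 (=1); exponent kept in log space
  expo <- function(x) -2 * N * s_prime * (2 * h * x + (1 - 2 * h) * x^2)
  psi <- function(x) exp(expo(x))
  num <- integrate(psi, 0, 1 / (2 * N), rel.tol = 1e-10)$value
  den <- integrate(psi, 0, 1, rel.tol = 1e-8)$value
  num / den
}

#' Monte Carlo fixation-probability check
#'
#' Runs conditioning-disabled replicates of a constant-size model with a
#' single initial copy and compares the empirical fixation frequency to
#' [kimura_fixation_probability()].  The check passes when the estimate
#' lies within `z_max` Monte Carlo standard errors of the prediction.
#'
#' @param N Constant diploid size.
#' @param s_prime Scaled selection coefficient.
#' @param h Dominance coefficient.
#' @param reps Number of replicates.
#' @param seed Base seed (per-replicate seeds are derived from it).
#' @param engine `"count"` (the C++ genotype-count engine) or
#'   `"individual"` (the oracle).
#' @param t_s Run length in 4N-generation units; must be long enough that
#'   unabsorbed trajectories are negligible (default 5, i.e. 20N
#'   generations).
#' @param z_max Pass threshold in standard errors (default 3).
#' @return List with `estimate`, `prediction`, `se`, `z`, `pass`, `reps`,
#'   and `warning` (non-NULL when `reps` is too small to resolve the
#'   prediction).
#' @export
fixation_probability_check <- function(N, s_prime, h = 0.5, reps = 1e4,
                                       seed = 1, engine = c("count",
                                                            "individual"),
                                       t_s = 5, z_max = 3) {
  engine <- match.arg(engine)
  model <- demographic_model("const_check", list(
    list(duration = NA, size_start = N, growth_rate = 0)))
  params <- sweep_params(s = s_prime, h = h, t_s = t_s, g = 0, Q = 1)
  runner <- if (engine == "count") run_replicate else
    individual_based_replicate
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)
  fixed <- vapply(seeds, function(sd)
    runner(model, params, seed = sd, condition = FALSE, G = 0,
           sample_n = 2L)$fixed, logical(1))
  u <- kimura_fixation_probability(N, s_prime, h)
  est <- mean(fixed)
  se <- sqrt(u * (1 - u) / reps)
  warn <- if (reps * u < 25)
    sprintf("only %.1f expected fixations; increase reps", reps * u) else NULL
  list(estimate = est, prediction = u, se = se, z = (est - u) / se,
       pass = abs(est - u) <= z_max * se, reps = reps, engine = engine,
       warning = warn)
}

#' Engine-vs-oracle distributional equivalence report
#'
#' Runs matched sets of replicates through the genotype-count engine and
#' the individual-based oracle and compares (i) fixation fraction and
#' pseudo-soft sample fraction by two-sided two-proportion z-tests and
#' (ii) the distribution of fixation times among fixed replicates by a
#' two-sample Kolmogorov-Smirnov test.
#'
#' @param model A rescaled-or-unscaled [demographic_model()] (small N!).
#' @param params A [sweep_params()].
#' @param reps Replicates per implementation.
#' @param seed Base seed.
#' @param alpha Significance level for the KS test (default 0.001).
#' @param sample_n Chromosomes sampled per replicate.
#' @return List with per-statistic estimates, z-values, KS p-value, and
#'   overall `pass`.
#' @export
engine_oracle_equivalence <- function(model, params, reps = 2000, seed = 1,
                                      alpha = 0.001, sample_n = 200L) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * reps),
                  ncol = 2L)
  run_set <- function(runner, col) {
    recs <- lapply(seq_len(reps), function(i)
      classify_replicate(runner(model, params, seed = seeds[i, col],
                                sample_n = sample_n)))
    do.call(rbind, recs)
  }
  eng <- run_set(run_replicate, 1L)
  ora <- run_set(individual_based_replicate, 2L)
  two_prop_z <- function(x1, x2) {
    p1 <- mean(x1); p2 <- mean(x2); p <- mean(c(x1, x2))
    den <- sqrt(p * (1 - p) * (2 / reps))
    if (den == 0) 0 else (p1 - p2) / den
  }
  z_fix <- two_prop_z(eng$fixed, ora$fixed)
  z_soft <- two_prop_z(eng$pseudo_soft_sample, ora$pseudo_soft_sample)
  ks <- suppressWarnings(ks.test(eng$gens_elapsed[eng$fixed],
                                 ora$gens_elapsed[ora$fixed]))
  list(engine_frac_fixed = mean(eng$fixed),
       oracle_frac_fixed = mean(ora$fixed),
       engine_frac_pseudo_soft = mean(eng$pseudo_soft_sample),
       oracle_frac_pseudo_soft = mean(ora$pseudo_soft_sample),
       z_fixed = z_fix, z_pseudo_soft = z_soft,
       ks_p_fixation_time = ks$p.value,
       pass = abs(z_fix) <= 3 && abs(z_soft) <= 3 && ks$p.value > alpha,
       reps = reps)
}
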