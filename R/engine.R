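## Genotype-count Wright-Fisher engine: user-facing reference
## implementations of the per-generation distributions plus the fast C++
## replicate runner.

#' Sweep scenario parameters
#'
#' Bundles the selection, dominance, timing, conversion and rescaling
#' parameters of one sweep scenario.  The engine uses the *scaled*
#' coefficients: selection `s' = s * Q` (genotype fitnesses 1 for bb,
#' 1 + h*s' for Bb, 1 + s' for BB) and per-gamete conversion probability
#' `G = 500 * g * c * Q`.
#'
#' @param s Unscaled selection coefficient (> 0 for a sweep; the published
#'   grid uses 0.001, 0.01, 0.1).
#' @param h Dominance coefficient (grid: 0, 0.5, 1).
#' @param t_s Sweep onset time in units of 4*N_A generations before
#'   present (grid: 0.01, 0.05, 0.1, 0.5, 1).
#' @param g Relative gene conversion multiplier (grid: 1, 5, 10, 50).
#' @param Q Rescaling factor applied to the demographic model.
#' @return An object of class `sweep_params`.
#' @export
sweep_params <- function(s, h, t_s, g = 1, Q = 1) {
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0,
            is.numeric(h), length(h) == 1L, h >= 0, h <= 1,
            is.numeric(t_s), length(t_s) == 1L, t_s > 0,
            is.numeric(g), length(g) == 1L, g >= 0,
            is.numeric(Q), length(Q) == 1L, Q >= 1)
  s_prime <- s * Q
  if (1 + h * s_prime <= 0 || 1 + s_prime <= 0)
    stop("scaled fitnesses must be positive (s' = ", s_prime, ")")
  structure(list(s = s, h = h, t_s = t_s, g = g, Q = as.integer(Q),
                 s_prime = s_prime),
            class = "sweep_params")
}

#' @export
print.sweep_params <- function(x, ...) {
  cat(sprintf("sweep_params: s=%g h=%g t_s=%g g=%g Q=%d (s'=%g)\n",
              x$s, x$h, x$t_s, x$g, x$Q, x$s_prime))
  invisible(x)
}

#' Gamete distribution of one diploid genotype
#'
#' A gamete is built by choosing one of the parent's two haplotypes
#' uniformly as the template; with probability `G` the allele at the
#' selected (B) locus is replaced by the homolog's B-locus allele, while
#' the neutral-marker (A) locus allele is always retained from the
#' template.  Conversion is silent when both haplotypes carry the same
#' B-locus allele, so `aB` gametes can only be produced by parents that
#' are heterozygous at the B locus and carry an `a` background.
#'
#' @param hap1,hap2 Haplotype names from `"AB"`, `"aB"`, `"Ab"`, `"ab"`.
#' @param G Per-meiosis conversion probability in \[0, 1).
#' @return Named numeric vector of probabilities over the four haplotypes.
#' @examples
#' gamete_distribution("AB", "ab", G = 0.1)
#' @export
gamete_distribution <- function(hap1, hap2, G) {
  stopifnot(is.numeric(G), length(G) == 1L, G >= 0, G < 1)
  h1 <- hap_code(hap1); h2 <- hap_code(hap2)
  out <- numeric(4)
  for (tpl in list(c(h1, h2), c(h2, h1))) {
    t <- tpl[1L]; o <- tpl[2L]
    A <- hap_carries_A(t)
    keep <- (if (hap_carries_B(t)) 0L else 2L) + (if (A) 0L else 1L)
    conv <- (if (hap_carries_B(o)) 0L else 2L) + (if (A) 0L else 1L)
    out[keep + 1L] <- out[keep + 1L] + 0.5 * (1 - G)
    out[conv + 1L] <- out[conv + 1L] + 0.5 * G
  }
  names(out) <- HAPLOTYPES
  out
}

#' Empty genotype count vector
#'
#' @return Named numeric vector of zeros over the 10 unordered two-locus
#'   genotypes, in the package's canonical order.
#' @export
genotype_counts <- function() {
  structure(numeric(10), names = GENOTYPES)
}

## coerce a (possibly partial) named genotype count vector to canonical order
as_genotype_counts <- function(counts) {
  if (is.null(names(counts))) {
    if (length(counts) != 10L) stop("unnamed counts must have length 10")
    return(structure(as.numeric(counts), names = GENOTYPES))
  }
  out <- genotype_counts()
  nm <- names(counts)
  ## accept "X/Y" in either haplotype order
  canon <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2L) stop("genotype names must look like 'AB/ab'")
      i <- sort(hap_code(p))
      paste(HAPLOTYPES[i + 1L], collapse = "/")
    }, character(1))
  }
  out[canon(nm)] <- as.numeric(counts)
  out
}

#' Offspring genotype distribution for one generation
#'
#' Each offspring is the unordered pair of two gametes; each gamete is
#' produced by an independently chosen parent, with parents drawn with
#' probability proportional to genotype fitness (1, 1 + h*s', 1 + s' for
#' bb, Bb, BB carriers) and gametes per [gamete_distribution()].  Because
#' the two gametes are iid draws from the fitness-weighted marginal gamete
#' distribution, the result is an exact 10-category distribution.
#'
#' @param counts Named genotype counts (see [genotype_counts()]); partial
#'   names are filled with zeros.
#' @param s_prime Scaled selection coefficient `s' = s * Q`.
#' @param h Dominance coefficient.
#' @param G Per-meiosis conversion probability.
#' @return Named numeric vector of probabilities over the 10 genotypes.
#' @examples
#' offspring_distribution(c("ab/ab" = 1, "AB/ab" = 1),
#'                        s_prime = 1, h = 0.5, G = 0)
#' @export
offspring_distribution <- function(counts, s_prime, h, G) {
  n <- as_genotype_counts(counts)
  if (sum(n) < 1) stop("at least one individual must be present")
  w_by_nB <- c(1, 1 + h * s_prime, 1 + s_prime)
  nB <- hap_carries_B(GENOTYPE_I - 1L) + hap_carries_B(GENOTYPE_J - 1L)
  w <- w_by_nB[nB + 1L]
  if (any(w <= 0)) stop("non-positive fitness weight")
  ## marginal gamete distribution
  q <- numeric(4)
  W <- 0
  for (gt in seq_len(10L)) {
    if (n[gt] == 0) next
    wg <- n[gt] * w[gt]
    W <- W + wg
    q <- q + wg * gamete_distribution(HAPLOTYPES[GENOTYPE_I[gt]],
                                      HAPLOTYPES[GENOTYPE_J[gt]], G)
  }
  q <- q / W
  p <- q[GENOTYPE_I] * q[GENOTYPE_J] * ifelse(GENOTYPE_I == GENOTYPE_J, 1, 2)
  structure(as.numeric(p), names = GENOTYPES)
}

#' Advance one Wright-Fisher generation
#'
#' Draws the next generation's genotype counts as a single multinomial
#' sample of `N_next` offspring from [offspring_distribution()].
#'
#' @inheritParams offspring_distribution
#' @param N_next Diploid size of the next generation (>= 2).
#' @return Named genotype counts summing to `N_next`.
#' @export
wf_step <- function(counts, s_prime, h, G, N_next) {
  stopifnot(is.numeric(N_next), length(N_next) == 1L, N_next >= 2)
  p <- offspring_distribution(counts, s_prime, h, G)
  structure(as.numeric(rmultinom(1L, size = N_next, prob = p)),
            names = GENOTYPES)
}

#' Run one sweep replicate
#'
#' Initializes the population at the sweep onset generation with a single
#' AB/ab heterozygote (one copy of the beneficial allele on the A marker
#' background) and N-1 ab/ab individuals, then iterates Wright-Fisher
#' generations with the deterministic size trajectory of `model`.  If the
#' beneficial allele is lost the replicate restarts from the onset (state
#' and clock reset; the random number stream continues), so every returned
#' replicate conditions on non-loss.  The replicate terminates when B
#' fixes or when the present (generation 0) is reached, whichever comes
#' first, and a uniform random sample of `min(sample_n, 2N)` chromosomes
#' is drawn without replacement from the final population.  No burn-in is
#' performed: all recorded outcomes depend only on the beneficial allele's
#' trajectory and the conversion events during its sojourn.
#'
#' @param model A [demographic_model()] already rescaled by `params$Q`.
#' @param params A [sweep_params()].
#' @param seed Optional integer seed (uses the current RNG state if
#'   `NULL`).
#' @param sample_n Number of chromosomes to sample at the end (default
#'   200).
#' @param condition Restart on loss of B (default `TRUE`).  Disabling
#'   conditioning is intended only for fixation-probability validation.
#' @param restart_cap Maximum number of restarts before aborting with an
#'   error (default 1e7).
#' @param G Optional override of the conversion probability; by default
#'   `conversion_probability(model$c, params$g, params$Q)`.
#' @param trajectory Record the per-generation haplotype counts of the
#'   returned attempt (default `FALSE`); see [write_trajectory()].
#' @return A `replicate_result`: list with `fixed`, `lost`,
#'   `gens_elapsed` (generations simulated in the returned attempt),
#'   `restarts`, `N_final`, `pop_counts` and `sample_counts` (named counts
#'   over AB/aB/Ab/ab), `sample_n`, and `p_f` (final population B
#'   frequency, 1 if fixed).  With `trajectory = TRUE` a
#'   `(gens_elapsed + 1) x 4` matrix of haplotype counts (onset first) is
#'   included as `trajectory`.
#' @examples
#' m <- rescale_model(build_model("human_constant"), 10)
#' r <- run_replicate(m, sweep_params(0.01, 0.5, t_s = 0.05, g = 1, Q = 10),
#'                    seed = 1)
#' r$pop_counts
#' @export
run_replicate <- function(model, params, seed = NULL, sample_n = 200L,
                          condition = TRUE, restart_cap = 1e7, G = NULL,
                          trajectory = FALSE) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(params, "sweep_params"))
  if (model$Q != params$Q)
    stop("model rescaling (Q = ", model$Q, ") does not match params (Q = ",
         params$Q, "); rescale the model first")
  if (is.null(G)) {
    if (is.na(model$c))
      stop("model '", model$name, "' has no crossover rate c; pass G directly")
    G <- if (params$g == 0) 0 else
      conversion_probability(model$c, params$g, params$Q)
  }
  T_onset <- onset_generation(model, params$t_s)
  if (T_onset < 1L) stop("sweep onset rounds to the present (t_s too small ",
                         "for this model/Q)")
  sizes <- size_at(model, seq.int(T_onset, 0L))
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_replicate(sizes, params$s_prime, params$h, G,
                           condition, restart_cap, trajectory)
  pop <- structure(res$pop_counts, names = HAPLOTYPES)
  two_n <- sum(pop)
  n_take <- min(sample_n, two_n)
  drawn <- sample(rep.int(seq_len(4L), pop), n_take)
  samp <- structure(as.numeric(tabulate(drawn, nbins = 4L)),
                    names = HAPLOTYPES)
  out <- list(fixed = res$fixed, lost = res$lost,
              gens_elapsed = res$gens_elapsed, restarts = res$restarts,
              N_final = res$N_final, pop_counts = pop,
              sample_counts = samp, sample_n = n_take, p_f = res$p_f,
              onset_generation = T_onset,
              params = params, model_name = model$name)
  if (trajectory) {
    colnames(res$trajectory) <- HAPLOTYPES
    out$trajectory <- res$trajectory
  }
  structure(out, class = "replicate_result")
}

#' Write a recorded trajectory as CSV
#'
#' Columns: `generation` (generations before present, onset first) and
#' the four haplotype counts `AB`, `aB`, `Ab`, `ab`.
#'
#' @param replicate A `replicate_result` from
#'   `run_replicate(..., trajectory = TRUE)`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(replicate, path) {
  stopifnot(inherits(replicate, "replicate_result"))
  if (is.null(replicate$trajectory))
    stop("replicate has no recorded trajectory; rerun with ",
         "trajectory = TRUE")
  tr <- replicate$trajectory
  onset <- replicate$onset_generation
  df <- data.frame(generation = seq.int(onset, onset - nrow(tr) + 1L), tr)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf("replicate_result: %s after %d generations (%g restarts)\n",
              if (x$fixed) "fixed" else if (x$lost) "lost" else
                "reached present", x$gens_elapsed, x$restarts))
  cat("  p_f =", format(x$p_f), "\n  population:",
      paste(names(x$pop_counts), x$pop_counts, sep = "=", collapse = " "),
      "\n  sample:    ",
      paste(names(x$sample_counts), x$sample_counts, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}
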