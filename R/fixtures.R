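## Deterministic fixtures: hand-specified haplotype samples and logistic
## allele-frequency trajectories, so outcome classification, aggregation
## and table export are testable without running the stochastic engine.

#' Build a deterministic replicate result from haplotype counts
#'
#' Constructs a `replicate_result` (the same shape [run_replicate()]
#' returns) directly from sample haplotype counts, with no randomness.
#'
#' @param counts Named counts over a subset of `"AB"`, `"aB"`, `"Ab"`,
#'   `"ab"` describing the sampled chromosomes.
#' @param fixed Logical; whether the beneficial allele had fixed.  If
#'   `TRUE`, `counts` must contain no b-carrying (`Ab`/`ab`) chromosomes.
#' @param n Sample size; defaults to `sum(counts)` and must match it.
#' @param pop_counts Optional named population haplotype counts; defaults
#'   to the sample counts (a "population equals sample" toy world).
#' @param gens_elapsed,restarts Bookkeeping fields (default 0).
#' @return A `replicate_result`.
#' @examples
#' classify_replicate(make_sample(c(AB = 190, aB = 10), fixed = TRUE))
#' @export
make_sample <- function(counts, fixed, n = sum(counts), pop_counts = NULL,
                        gens_elapsed = 0L, restarts = 0) {
  full <- structure(numeric(4), names = HAPLOTYPES)
  if (is.null(names(counts))) stop("counts must be named by haplotype")
  hap_code(names(counts))  # validates names
  full[names(counts)] <- as.numeric(counts)
  if (any(full < 0)) stop("counts must be non-negative")
  if (sum(full) != n) stop("counts sum to ", sum(full), ", not n = ", n)
  if (n < 1) stop("sample must contain at least one chromosome")
  pop <- if (is.null(pop_counts)) full else {
    p <- structure(numeric(4), names = HAPLOTYPES)
    hap_code(names(pop_counts))
    p[names(pop_counts)] <- as.numeric(pop_counts)
    p
  }
  if (isTRUE(fixed) && (full[["Ab"]] > 0 || full[["ab"]] > 0 ||
                        pop[["Ab"]] > 0 || pop[["ab"]] > 0))
    stop("a fixed sweep cannot contain b-carrying chromosomes")
  p_f <- (pop[["AB"]] + pop[["aB"]]) / sum(pop)
  structure(list(fixed = isTRUE(fixed), lost = FALSE,
                 gens_elapsed = as.integer(gens_elapsed),
                 restarts = restarts, N_final = sum(pop) / 2,
                 pop_counts = pop, sample_counts = full, sample_n = n,
                 p_f = if (isTRUE(fixed)) 1 else p_f,
                 params = NULL, model_name = "fixture"),
            class = "replicate_result")
}

#' Deterministic logistic sweep trajectory
#'
#' The closed-form logistic frequency curve
#' `p(t) = p0 * exp(s'*t) / (1 + p0 * (exp(s'*t) - 1))`, a deterministic
#' stand-in for a sweeping allele's trajectory, monotone non-decreasing
#' for `s' > 0`.
#'
#' @param p0 Initial frequency in (0, 1).
#' @param s_prime Scaled selection coefficient (logistic growth rate).
#' @param length Number of generations; the series is returned for
#'   t = 0, 1, ..., `length`.
#' @return Numeric vector of length `length + 1`.
#' @examples
#' logistic_trajectory(0.01, 0.1, 100)[101]  # ~0.9955
#' @export
logistic_trajectory <- function(p0, s_prime, length) {
  if (!is.numeric(p0) || length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly between 0 and 1")
  stopifnot(is.numeric(s_prime), length(s_prime) == 1L,
            is.numeric(length), length(length) == 1L, length >= 1)
  t <- 0:length
  e <- exp(s_prime * t)
  p0 * e / (1 + p0 * (e - 1))
}

#' Load a shipped named fixture
#'
#' Reads one of the deterministic haplotype-sample fixtures serialized in
#' `inst/extdata/fixtures/fixtures.json` and materializes it via
#' [make_sample()].  The shipped set covers every outcome code path:
#' fixed/unfixed, hard/pseudo-soft, original haplotype lost, and the
#' empty-median edge case.
#'
#' @param name Fixture name; call with `name = NULL` to list names.
#' @return A `replicate_result`, or a character vector of names.
#' @export
load_fixture <- function(name = NULL) {
  path <- system.file("extdata", "fixtures", "fixtures.json",
                      package = "sweepconv", mustWork = TRUE)
  specs <- jsonlite::read_json(path)
  if (is.null(name)) return(vapply(specs, `[[`, character(1), "name"))
  hit <- Filter(function(s) identical(s$name, name), specs)
  if (length(hit) != 1L)
    stop("unknown fixture '", name, "'; available: ",
         paste(vapply(specs, `[[`, character(1), "name"), collapse = ", "))
  s <- hit[[1L]]
  make_sample(unlist(s$counts), fixed = isTRUE(s$fixed),
              pop_counts = if (is.null(s$pop_counts)) NULL
                           else unlist(s$pop_counts))
}
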