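## Outcome classification (hard vs pseudo-soft) and per-scenario summaries.

#' Classify a replicate as hard or pseudo-soft
#'
#' A sweep is pseudo-soft if at least one recombinant `aB` haplotype is
#' present in the pool under consideration (whole population or the
#' 200-chromosome sample) at the end of the replicate.  For unfixed
#' replicates the softness of the partial sweep is measured as the
#' fraction of `a` alleles among the sampled B-carrying chromosomes.
#'
#' @param replicate A `replicate_result` from [run_replicate()],
#'   [individual_based_replicate()] or [make_sample()].
#' @return One-row data.frame (`outcome_record`) with columns `fixed`,
#'   `pseudo_soft_pop`, `pseudo_soft_sample`, `aB_freq_pop`,
#'   `aB_freq_sample`, `p_f`, `a_among_B_sample` (NA when the sample has
#'   no B-carrying chromosome), `original_lost` (fixed, AB absent from the
#'   sample while aB present), `restarts`, `gens_elapsed`.
#' @examples
#' classify_replicate(make_sample(c(AB = 195, aB = 5), fixed = TRUE))
#' @export
classify_replicate <- function(replicate) {
  stopifnot(inherits(replicate, "replicate_result"))
  pop <- replicate$pop_counts
  samp <- replicate$sample_counts
  two_n <- sum(pop)
  n <- sum(samp)
  b_samp <- samp[["AB"]] + samp[["aB"]]
  data.frame(
    fixed = replicate$fixed,
    pseudo_soft_pop = pop[["aB"]] >= 1,
    pseudo_soft_sample = samp[["aB"]] >= 1,
    aB_freq_pop = pop[["aB"]] / two_n,
    aB_freq_sample = samp[["aB"]] / n,
    p_f = replicate$p_f,
    a_among_B_sample = if (b_samp >= 1) samp[["aB"]] / b_samp else NA_real_,
    original_lost = replicate$fixed && samp[["AB"]] == 0 && samp[["aB"]] > 0,
    restarts = replicate$restarts,
    gens_elapsed = replicate$gens_elapsed)
}

#' Aggregate outcome records into a scenario summary row
#'
#' Fractions of pseudo-soft sweeps are computed over *all* replicates
#' (fixed and unfixed), as are mean final beneficial-allele frequencies;
#' the median recombinant (`aB`) sample frequency and the fraction of
#' sweeps that lost the original unconverted haplotype are computed over
#' replicates that both fixed and were pseudo-soft in the sample.
#'
#' @param records A data.frame of rows from [classify_replicate()] (rbind
#'   of outcome records).
#' @param scenario Optional named list/data.frame of scenario keys (model,
#'   s, h, t_s, g, Q, ...) prepended to the summary row.
#' @return One-row data.frame with the scenario keys plus `n_reps`,
#'   `n_fixed`, `frac_pseudo_soft_sample`, `frac_pseudo_soft_pop`,
#'   `mean_p_f`, `median_aB_freq_fixed_pseudo_soft` (NA when no replicate
#'   is both fixed and pseudo-soft), `frac_original_lost` (same
#'   denominator).
#' @export
aggregate_outcomes <- function(records, scenario = NULL) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot aggregate an empty set of outcome records")
  fp <- records$fixed & records$pseudo_soft_sample
  out <- data.frame(
    n_reps = nrow(records),
    n_fixed = sum(records$fixed),
    frac_pseudo_soft_sample = mean(records$pseudo_soft_sample),
    frac_pseudo_soft_pop = mean(records$pseudo_soft_pop),
    mean_p_f = mean(records$p_f),
    median_aB_freq_fixed_pseudo_soft =
      if (any(fp)) median(records$aB_freq_sample[fp]) else NA_real_,
    frac_original_lost =
      if (any(fp)) mean(records$original_lost[fp]) else NA_real_)
  if (!is.null(scenario)) out <- cbind(as.data.frame(scenario), out)
  out
}

#' Bootstrap confidence interval for a median
#'
#' Nonparametric percentile bootstrap CI of the sample median, used to
#' compare simulated recombinant-haplotype frequency medians against
#' published point values.
#'
#' @param x Numeric vector.
#' @param conf Confidence level (default 0.95).
#' @param B Number of bootstrap resamples (default 2000).
#' @return List with `median`, `lower`, `upper`, `conf`, `B`.
#' @export
bootstrap_median_ci <- function(x, conf = 0.95, B = 2000L) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least two observations")
  meds <- vapply(seq_len(B), function(i)
    median(x[sample.int(length(x), replace = TRUE)]), numeric(1))
  qs <- quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(median = median(x), lower = qs[1L], upper = qs[2L], conf = conf,
       B = B)
}

#' Write scenario summaries as TSV (with JSON mirror)
#'
#' @param summary Data.frame of summary rows ([aggregate_outcomes()]).
#' @param path Output TSV path; a `.json` mirror is written next to it.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, paste0(tools::file_path_sans_ext(path), ".json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(path)
}
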