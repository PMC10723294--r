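## Scenario and grid runners reproducing the published parameter
## combinations, plus tidy per-figure table export.

#' Default Q-rescaling factor for a model
#'
#' 10 for the human and *A. thaliana* models, 100 for *D. melanogaster*.
#'
#' @param model_name A shipped model name (see [build_model()]).
#' @return Integer Q.
#' @export
default_Q <- function(model_name) build_model(model_name)$default_Q

#' Run one sweep scenario
#'
#' Builds and rescales the demographic model, derives the scaled engine
#' parameters, runs replicates with per-replicate seeds derived from
#' `base_seed`, classifies each replicate, and aggregates.  When
#' `min_fixed_pseudo_soft` is given, additional batches of `reps`
#' replicates are run (up to `max_reps` in total) until at least that many
#' replicates are both fixed and pseudo-soft in the sample — used for
#' recombinant-frequency medians, which condition on that subset.
#'
#' @param model_name A shipped model name (see [build_model()]) or a
#'   [demographic_model()] object (rescaled here when `Q > 1`).
#' @param s,h,t_s,g Sweep parameters (see [sweep_params()]).
#' @param Q Rescaling factor; defaults to the model's conventional value
#'   (or to the object's current `Q`).
#' @param reps Replicates per batch (the published grids use 1000).
#' @param base_seed Integer seed from which per-replicate seeds are drawn.
#' @param sample_n Chromosomes sampled per replicate (default 200).
#' @param min_fixed_pseudo_soft Optional target count of fixed pseudo-soft
#'   replicates.
#' @param max_reps Hard cap on total replicates in the batched mode.
#' @param restart_cap Per-replicate restart cap (see [run_replicate()]).
#' @param keep_records Return per-replicate outcome records as an
#'   attribute.
#' @return One-row summary data.frame (see [aggregate_outcomes()]); when
#'   `keep_records = TRUE` the per-replicate records data.frame is
#'   attached as `attr(, "records")`.
#' @examples
#' \donttest{
#' run_scenario("human_constant", s = 0.01, h = 1, t_s = 0.05, g = 1,
#'              reps = 50, base_seed = 1)
#' }
#' @export
run_scenario <- function(model_name, s, h, t_s, g = 1, Q = NULL,
                         reps = 1000L, base_seed = 1L, sample_n = 200L,
                         min_fixed_pseudo_soft = NULL, max_reps = 20L * reps,
                         restart_cap = 1e7, keep_records = FALSE) {
  if (inherits(model_name, "demographic_model")) {
    model <- model_name
    if (is.null(Q)) Q <- model$Q
    if (model$Q == 1L && Q > 1) model <- rescale_model(model, Q)
    if (model$Q != Q) stop("model is rescaled by Q = ", model$Q,
                           " but Q = ", Q, " was requested")
    model_name <- model$name
  } else {
    if (is.null(Q)) Q <- default_Q(model_name)
    model <- rescale_model(build_model(model_name), Q)
  }
  params <- sweep_params(s = s, h = h, t_s = t_s, g = g, Q = Q)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, max(reps, max_reps))
  run_batch <- function(idx) {
    do.call(rbind, lapply(idx, function(i)
      cbind(rep_index = i,
            classify_replicate(run_replicate(model, params,
                                             seed = seeds[i],
                                             sample_n = sample_n,
                                             restart_cap = restart_cap)))))
  }
  records <- run_batch(seq_len(reps))
  if (!is.null(min_fixed_pseudo_soft)) {
    while (sum(records$fixed & records$pseudo_soft_sample) <
             min_fixed_pseudo_soft && nrow(records) + reps <= max_reps) {
      records <- rbind(records,
                       run_batch(seq.int(nrow(records) + 1L,
                                         nrow(records) + reps)))
    }
    if (sum(records$fixed & records$pseudo_soft_sample) <
          min_fixed_pseudo_soft)
      warning("reached max_reps = ", max_reps, " with only ",
              sum(records$fixed & records$pseudo_soft_sample),
              " fixed pseudo-soft replicates")
  }
  scenario <- list(model = model_name, s = s, h = h, t_s = t_s, g = g,
                   Q = Q, base_seed = base_seed)
  out <- aggregate_outcomes(records, scenario)
  if (keep_records) attr(out, "records") <- records
  out
}

#' Grid configuration
#'
#' The default grid is the published one: all combinations of
#' `s` in \{0.001, 0.01, 0.1\}, `h` in \{0, 0.5, 1\},
#' `t_s` in \{0.01, 0.05, 0.1, 0.5, 1\}, `g` in \{1, 5, 10, 50\},
#' 1000 replicates each, with the conventional Q per model.  The
#' `"desk"` profile reduces to 200 replicates for CI-scale runs.
#'
#' @param models Character vector of shipped model names.
#' @param s,h,t_s,g Parameter value vectors (crossed).
#' @param reps Replicates per combination.
#' @param base_seed Integer base seed.
#' @param profile `"paper"` (1000 reps) or `"desk"` (200 reps); explicit
#'   `reps` overrides the profile.
#' @return A `grid_config` list.
#' @export
grid_config <- function(models = "human_constant",
                        s = c(0.001, 0.01, 0.1), h = c(0, 0.5, 1),
                        t_s = c(0.01, 0.05, 0.1, 0.5, 1),
                        g = c(1, 5, 10, 50), reps = NULL, base_seed = 1L,
                        profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  if (is.null(reps)) reps <- if (profile == "paper") 1000L else 200L
  stopifnot(all(models %in% MODEL_NAMES), all(s > 0), all(h >= 0 & h <= 1),
            all(t_s > 0), all(g >= 0), reps >= 1)
  structure(list(models = models, s = s, h = h, t_s = t_s, g = g,
                 reps = as.integer(reps), base_seed = as.integer(base_seed),
                 profile = profile),
            class = "grid_config")
}

#' Read a grid configuration from JSON
#'
#' @param path JSON file with any subset of the [grid_config()] fields.
#' @return A `grid_config`.
#' @export
read_grid_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(grid_config, js[intersect(names(js),
                                    names(formals(grid_config)))])
}

#' Run a full scenario grid
#'
#' One [run_scenario()] call per (model, s, h, t_s, g) combination.
#' Per-scenario seeds are derived deterministically from the base seed and
#' the scenario index, so the grid is reproducible and the scenarios are
#' independent.  A scenario whose restart cap trips is recorded with
#' `status = "failed"` and NA statistics instead of aborting the grid.
#'
#' @param config A [grid_config()].
#' @param keep_records Also return the per-replicate records (list indexed
#'   by scenario) as `attr(, "records")`.
#' @param quiet Suppress progress messages to stderr.
#' @param ... Passed to [run_scenario()] (e.g. `restart_cap`,
#'   `sample_n`).
#' @return Data.frame with one row per scenario (summary columns from
#'   [aggregate_outcomes()] plus `status`).
#' @export
run_grid <- function(config, keep_records = FALSE, quiet = TRUE, ...) {
  stopifnot(inherits(config, "grid_config"))
  combos <- expand.grid(model = config$models, s = config$s, h = config$h,
                        t_s = config$t_s, g = config$g,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  set.seed(config$base_seed)
  scen_seeds <- sample.int(.Machine$integer.max - 1L, nrow(combos))
  rows <- vector("list", nrow(combos))
  recs <- if (keep_records) vector("list", nrow(combos)) else NULL
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    if (!quiet)
      message(sprintf("[%d/%d] %s s=%g h=%g t_s=%g g=%g", i, nrow(combos),
                      cb$model, cb$s, cb$h, cb$t_s, cb$g))
    res <- tryCatch(
      run_scenario(cb$model, s = cb$s, h = cb$h, t_s = cb$t_s, g = cb$g,
                   reps = config$reps, base_seed = scen_seeds[i],
                   keep_records = keep_records, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("scenario ", i, " (", cb$model, ") failed: ",
              conditionMessage(res))
      row <- cbind(data.frame(model = cb$model, s = cb$s, h = cb$h,
                              t_s = cb$t_s, g = cb$g,
                              Q = default_Q(cb$model),
                              base_seed = scen_seeds[i]),
                   aggregate_na_row())
      row$status <- "failed"
    } else {
      if (keep_records) {
        recs[[i]] <- attr(res, "records")
        attr(res, "records") <- NULL
      }
      row <- res
      row$status <- "ok"
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (keep_records) attr(out, "records") <- recs
  out
}

aggregate_na_row <- function() {
  data.frame(n_reps = NA_integer_, n_fixed = NA_integer_,
             frac_pseudo_soft_sample = NA_real_,
             frac_pseudo_soft_pop = NA_real_, mean_p_f = NA_real_,
             median_aB_freq_fixed_pseudo_soft = NA_real_,
             frac_original_lost = NA_real_)
}

#' Export per-figure tidy tables
#'
#' Reshapes a grid summary into the layouts behind the published figures:
#' pseudo-soft fractions by species and s x h at t_s = 1 (`fig2`); the
#' full fraction surface by t_s x s x h x g per model (`fig3to5`); and,
#' when per-replicate records are supplied, the distributions of
#' recombinant (aB) sample frequencies among fixed pseudo-soft replicates
#' at t_s = 1 (`fig6`).  Tables are written as TSV files under `out_dir`;
#' scenarios missing from `summary` are listed in a `warnings.txt`
#' sidecar and partial output is still written.
#'
#' @param summary Grid summary data.frame from [run_grid()].
#' @param out_dir Output directory (created if needed).
#' @param records Optional list of per-replicate record data.frames
#'   (`attr(run_grid(...), "records")`).
#' @return Invisible character vector of written file paths.
#' @export
figure_tables <- function(summary, out_dir, records = NULL) {
  if (is.null(summary) || nrow(summary) == 0L)
    stop("empty grid summary")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  warn <- character(0)

  fig2 <- summary[summary$t_s == 1,
                  c("model", "s", "h", "g", "frac_pseudo_soft_sample",
                    "mean_p_f")]
  if (nrow(fig2) == 0L)
    warn <- c(warn, "no t_s = 1 scenarios; fig2 table empty")
  p <- file.path(out_dir, "fig2_fractions_ts1.tsv")
  write.table(fig2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  for (m in unique(summary$model)) {
    sub <- summary[summary$model == m,
                   c("model", "t_s", "s", "h", "g",
                     "frac_pseudo_soft_sample", "mean_p_f")]
    p <- file.path(out_dir, paste0("fig3to5_fractions_", m, ".tsv"))
    write.table(sub[order(sub$t_s, sub$s, sub$h, sub$g), ], p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (!is.null(records)) {
    keep <- which(summary$t_s == 1)
    if (length(keep) == 0L) {
      warn <- c(warn, "no t_s = 1 scenarios; fig6 table skipped")
    } else {
      freq <- do.call(rbind, lapply(keep, function(i) {
        r <- records[[i]]
        if (is.null(r)) return(NULL)
        fp <- r$fixed & r$pseudo_soft_sample
        if (!any(fp)) return(NULL)
        data.frame(model = summary$model[i], s = summary$s[i],
                   h = summary$h[i], g = summary$g[i],
                   aB_freq_sample = r$aB_freq_sample[fp])
      }))
      p <- file.path(out_dir, "fig6_aB_freq_distributions_ts1.tsv")
      if (is.null(freq)) {
        warn <- c(warn, "no fixed pseudo-soft replicates at t_s = 1")
      } else {
        write.table(freq, p, sep = "\t", quote = FALSE, row.names = FALSE)
        paths <- c(paths, p)
      }
    }
  }

  if (length(warn)) {
    wp <- file.path(out_dir, "warnings.txt")
    writeLines(warn, wp)
    paths <- c(paths, wp)
  }
  invisible(paths)
}
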