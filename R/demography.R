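## Demographic histories: piecewise (constant or exponential-growth) epochs,
## Q-rescaling, and the composite gene-conversion parameter.
##
## Time convention: integer generations before present; generation 0 is the
## present, and the simulation runs forward from `onset_generation()` down
## to 0.  Epochs are stored oldest -> newest; the oldest epoch extends
## indefinitely into the past (duration NA) and must have growth rate 0.
## Within a growth epoch, size_start is the size at the epoch's *oldest*
## boundary and the size t generations later is round(size_start * exp(r*t)).

#' Construct a piecewise demographic model
#'
#' Builds a `demographic_model` object from a list of epochs ordered oldest
#' to newest.  Most users should call [build_model()], which loads the
#' shipped species histories; this constructor exists for custom (e.g.
#' toy constant-size) models.
#'
#' @param name Identifier for the model.
#' @param epochs List of epochs, oldest first.  Each epoch is a list with
#'   `duration` (generations; `NA`/`NULL` for the unbounded oldest epoch),
#'   `size_start` (diploid size at the epoch's oldest boundary) and
#'   `growth_rate` (per-generation exponential rate, 0 for constant).
#' @param c Per-base-pair mean crossover rate for the species (used to
#'   derive the composite conversion probability); may be `NA` for toy
#'   models if conversion parameters are supplied directly.
#' @param default_Q Conventional rescaling factor for this model.
#' @param citation Free-text provenance note.
#' @return A `demographic_model`: list with fields `name`, `epochs`
#'   (data.frame with columns `duration`, `size_start`, `growth_rate`,
#'   `start_bp` = generations before present of the epoch's oldest
#'   boundary), `N_A`, `N_A_unscaled`, `Q`, `c`, `default_Q`, `citation`.
#' @examples
#' toy <- demographic_model("toy", list(
#'   list(duration = NA, size_start = 100, growth_rate = 0)))
#' size_at(toy, 0:5)
#' @export
demographic_model <- function(name, epochs, c = NA_real_, default_Q = 1L,
                              citation = "") {
  if (length(epochs) < 1L) stop("need at least one epoch")
  dur <- vapply(epochs, function(e) {
    d <- e$duration
    if (is.null(d) || is.na(d)) NA_real_ else as.numeric(d)
  }, numeric(1))
  size <- vapply(epochs, function(e) as.numeric(e$size_start), numeric(1))
  rate <- vapply(epochs, function(e) as.numeric(e$growth_rate), numeric(1))
  if (!is.na(dur[1L])) stop("oldest epoch must be unbounded (duration NA)")
  if (length(dur) > 1L && anyNA(dur[-1L]))
    stop("only the oldest epoch may have unbounded duration")
  if (length(dur) > 1L && any(dur[-1L] < 1))
    stop("epoch durations must be >= 1 generation")
  if (rate[1L] != 0) stop("oldest (unbounded) epoch must have growth rate 0")
  if (any(size < 2)) stop("epoch sizes must be >= 2 diploid individuals")
  ## oldest boundary of epoch k = summed durations of epochs k..K
  ## (generations before present); the unbounded oldest epoch gets Inf.
  bp <- c(Inf, rev(cumsum(rev(dur[-1L]))))
  ep <- data.frame(duration = dur, size_start = size, growth_rate = rate,
                   start_bp = bp)
  structure(list(name = name, epochs = ep, N_A = round(size[1L]),
                 N_A_unscaled = round(size[1L]), Q = 1L,
                 c = c, default_Q = as.integer(default_Q),
                 citation = citation),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model '%s' (Q = %d, N_A = %d)\n",
              x$name, x$Q, x$N_A))
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

MODEL_NAMES <- c("human_constant", "human_AFR_tennessen", "human_EUR_tennessen",
                 "dmel_constant", "dmel_3epoch_sheehan",
                 "athal_constant", "athal_3epoch_SMA")

#' Load a shipped demographic model
#'
#' Returns the unscaled (Q = 1) demographic history for one of the seven
#' modeled scenarios: constant-size human (N = 10,000), the AFR and EUR
#' single-population trajectories of the Tennessen et al. (2012)
#' out-of-Africa model, constant-size *D. melanogaster* (N = 1,720,600),
#' the Sheehan & Song (2016) African three-epoch bottleneck model,
#' constant-size *A. thaliana* (N = 10,000), and the Huber et al. (2018)
#' South Middle Atlas three-epoch model.  Multi-epoch parameters are
#' transcribed from the stdpopsim catalog; the EUR/AFR trajectories carry
#' no migration.
#'
#' @param name One of `human_constant`, `human_AFR_tennessen`,
#'   `human_EUR_tennessen`, `dmel_constant`, `dmel_3epoch_sheehan`,
#'   `athal_constant`, `athal_3epoch_SMA`.
#' @return A [demographic_model()] with `Q = 1`.
#' @examples
#' build_model("human_constant")$N_A    # 10000
#' build_model("dmel_constant")$N_A     # 1720600
#' @export
build_model <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% MODEL_NAMES))
    stop("unknown model '", paste(name, collapse = ","), "'; valid names: ",
         paste(MODEL_NAMES, collapse = ", "))
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "sweepconv", mustWork = TRUE)
  read_model(path)
}

#' Read a demographic model from a JSON file
#'
#' @param path Path to a JSON file with fields `name`, `epochs` (oldest
#'   first, each with `duration`, `size_start`, `growth_rate`), and
#'   optionally `c`, `default_Q`, `citation`.
#' @return A [demographic_model()].
#' @export
read_model <- function(path) {
  js <- jsonlite::read_json(path)
  demographic_model(js$name, js$epochs,
                    c = if (is.null(js$c)) NA_real_ else js$c,
                    default_Q = if (is.null(js$default_Q)) 1L else js$default_Q,
                    citation = if (is.null(js$citation)) "" else js$citation)
}

#' Write a demographic model to a JSON file
#'
#' @param model A [demographic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "demographic_model"))
  ep <- lapply(seq_len(nrow(model$epochs)), function(k) {
    d <- model$epochs$duration[k]
    list(duration = if (is.na(d)) NULL else d,
         size_start = model$epochs$size_start[k],
         growth_rate = model$epochs$growth_rate[k])
  })
  jsonlite::write_json(
    list(name = model$name, citation = model$citation, c = model$c,
         default_Q = model$default_Q, Q = model$Q, epochs = ep),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rescale a demographic model by a factor Q
#'
#' Divides every epoch size and duration by `Q` (rounding to the nearest
#' integer, with minimum size 2 and minimum duration 1) and multiplies
#' per-generation growth rates by `Q` so the rescaled trajectory traces
#' the original one.  The unscaled ancestral size is retained in
#' `N_A_unscaled` so that sweep onset times in units of 4*N_A generations
#' refer to the unscaled model.  Selection and conversion parameters must
#' be scaled separately (`s' = s*Q`, `G = 500*g*c*Q`); see
#' [sweep_params()] and [conversion_probability()].
#'
#' @param model An unscaled (`Q = 1`) [demographic_model()].
#' @param Q Positive integer rescaling factor.
#' @return The rescaled model, with `Q` recorded.
#' @examples
#' rescale_model(build_model("human_constant"), 10)$N_A  # 1000
#' @export
rescale_model <- function(model, Q) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 1 || Q != round(Q))
    stop("Q must be a positive integer (got ", format(Q), ")")
  if (model$Q != 1L) stop("model '", model$name, "' is already rescaled (Q = ",
                          model$Q, "); rescale the unscaled model instead")
  Q <- as.integer(Q)
  if (Q == 1L) return(model)
  ep <- model$epochs
  ep$size_start <- pmax(2, round(ep$size_start / Q))
  ep$duration <- ifelse(is.na(ep$duration), NA, pmax(1, round(ep$duration / Q)))
  ep$growth_rate <- ep$growth_rate * Q
  out <- demographic_model(model$name,
                           lapply(seq_len(nrow(ep)), function(k)
                             list(duration = ep$duration[k],
                                  size_start = ep$size_start[k],
                                  growth_rate = ep$growth_rate[k])),
                           c = model$c, default_Q = model$default_Q,
                           citation = model$citation)
  out$Q <- Q
  out$N_A_unscaled <- model$N_A_unscaled
  out
}

#' Diploid population size at a given generation
#'
#' Evaluates the piecewise size trajectory.  Vectorized over
#' `gens_before_present`; the oldest epoch extends indefinitely, so any
#' non-negative generation index is valid.
#'
#' @param model A [demographic_model()].
#' @param gens_before_present Non-negative integer generation(s);
#'   0 = present.
#' @return Integer vector of rounded diploid sizes (>= 2).
#' @export
size_at <- function(model, gens_before_present) {
  stopifnot(inherits(model, "demographic_model"))
  t <- as.numeric(gens_before_present)
  if (any(t < 0)) stop("gens_before_present must be non-negative")
  ep <- model$epochs
  K <- nrow(ep)
  ## epoch k (oldest first) covers generations [edges[k+1], edges[k]);
  ## edges are the decreasing oldest boundaries, newest epoch reaches 0.
  edges <- ep$start_bp
  idx <- rep.int(K, length(t))
  if (K > 1L) for (k in rev(seq_len(K - 1L))) idx[t >= edges[k + 1L]] <- k
  elapsed <- ifelse(is.finite(edges[idx]), edges[idx] - t, 0)
  sz <- round(ep$size_start[idx] * exp(ep$growth_rate[idx] * elapsed))
  as.integer(pmax(2, sz))
}

#' Generation at which a sweep begins
#'
#' Converts a sweep onset time expressed in units of 4*N_A generations
#' before the present (N_A = ancestral size of the *unscaled* model) into
#' an integer generation index of the (possibly rescaled) model:
#' `round(t_s * 4 * N_A_unscaled / Q)`.
#'
#' @param model A [demographic_model()] (rescaled or not).
#' @param t_s Positive onset time in units of 4*N_A generations.
#' @return Integer generations before present.
#' @examples
#' onset_generation(build_model("human_constant"), 1)              # 40000
#' onset_generation(rescale_model(build_model("human_constant"), 10), 0.05) # 200
#' @export
onset_generation <- function(model, t_s) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.numeric(t_s) || length(t_s) != 1L || is.na(t_s) || t_s <= 0)
    stop("t_s must be a positive number")
  as.integer(round(t_s * 4 * model$N_A_unscaled / model$Q))
}

#' Composite per-meiosis gene conversion probability
#'
#' The probability that the selected site's allele is gene-converted in a
#' transmitted gamete: `G = 500 * g * c * Q`, the product of a baseline
#' per-bp conversion rate of 500 times the species' mean crossover rate
#' `c`, a relative multiplier `g`, and the simulation rescaling factor
#' `Q`.  With the species rates shipped in the model files the baseline
#' (g = 1, Q = 1) values are 6.55e-6 (human), 8.98e-6 (*D. melanogaster*)
#' and 4.03e-7 (*A. thaliana*).
#'
#' @param c Per-base-pair mean crossover rate (> 0).
#' @param g Relative conversion-rate multiplier (>= 0; the published grid
#'   uses 1, 5, 10 and 50).
#' @param Q Rescaling factor (>= 1).
#' @return `G`, a probability in \[0, 1).
#' @export
conversion_probability <- function(c, g, Q = 1) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c <= 0)
    stop("c must be a positive per-bp rate")
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g < 0)
    stop("g must be a non-negative multiplier")
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 1)
    stop("Q must be >= 1")
  G <- 500 * g * c * Q
  if (G >= 1) stop("composite conversion probability G = ", format(G),
                   " >= 1 is not a valid per-meiosis probability")
  G
}
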