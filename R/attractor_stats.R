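#' Attractor period distribution of an ensemble
#'
#' Tallies the exact attractor periods of `n_trials` random
#' (matrix, initial state) pairs under discrete dynamics. Period 1 is a
#' fixed point; periods >= 2 are limit cycles. On the `pm1` map the
#' antisymmetry of the dynamics (negating the state negates the trajectory
#' when net inputs never vanish) makes even-length cycles strongly
#' overrepresented, so even and odd cycle counts are reported separately.
#'
#' @inheritParams run_trials
#' @return an object of class `period_distribution`: `periods` (sorted
#'   distinct periods), `counts`, `total` (resolved runs), `map`,
#'   `even_cycles` / `odd_cycles` (cycle counts by parity), `n_unresolved`.
#' @export
period_distribution <- function(ens, dyn, n_trials, seed = NULL) {
  if (dyn$norm != "step")
    stop("period distributions need discrete (step) dynamics: continuous periods are tolerance-limited",
         call. = FALSE)
  trials <- run_trials(ens, dyn, n_trials, seed)
  periods <- trials$period[trials$outcome != "unresolved"]
  if (length(periods) == 0)
    stop("all runs were unresolved; nothing to tabulate", call. = FALSE)
  tab <- table(periods)
  period_distribution_from_counts(as.integer(names(tab)), as.integer(tab),
                                  map = dyn$map,
                                  n_unresolved = sum(trials$outcome ==
                                                       "unresolved"))
}

#' @rdname period_distribution
#' @param periods integer vector of distinct periods.
#' @param counts attractor counts per period.
#' @param map state map tag carried for parity-aware fitting.
#' @param n_unresolved censored-run count to record.
#' @export
period_distribution_from_counts <- function(periods, counts, map = "pm1",
                                            n_unresolved = 0L) {
  stopifnot(length(periods) == length(counts), all(periods >= 1),
            all(counts >= 0))
  o <- order(periods)
  periods <- as.integer(periods[o]); counts <- as.integer(counts[o])
  cyc <- periods >= 2L
  structure(
    list(periods = periods, counts = counts, total = sum(counts),
         map = map,
         even_cycles = sum(counts[cyc & periods %% 2L == 0L]),
         odd_cycles = sum(counts[cyc & periods %% 2L == 1L]),
         n_unresolved = as.integer(n_unresolved)),
    class = "period_distribution")
}

#' @export
print.period_distribution <- function(x, ...) {
  cat(sprintf("<period_distribution> %d attractors over %d periods (map %s)\n",
              x$total, length(x$periods), x$map))
  cat(sprintf("  cycles: %d even, %d odd; %d unresolved runs\n",
              x$even_cycles, x$odd_cycles, x$n_unresolved))
  invisible(x)
}

#' Even-over-odd period frequency ratios
#'
#' Computes `f(L) / f(L + 1)` for even cycle lengths `L`: the factor by
#' which a cycle of even length L is more frequent than one of the next odd
#' length. On the `pm1` map these ratios are expected to be at least 2.
#'
#' @param dist a `period_distribution`.
#' @param lengths even cycle lengths to report.
#' @return named numeric vector of ratios (`Inf` when `f(L + 1) = 0`,
#'   `NA` when `f(L) = 0` too).
#' @export
even_odd_ratios <- function(dist, lengths = c(2L, 4L, 6L)) {
  stopifnot(inherits(dist, "period_distribution"),
            all(lengths %% 2 == 0))
  freq_of <- function(L) {
    i <- match(L, dist$periods)
    if (is.na(i)) 0 else dist$counts[i] / dist$total
  }
  ratios <- vapply(lengths, function(L) {
    fe <- freq_of(L); fo <- freq_of(L + 1L)
    if (fe == 0 && fo == 0) NA_real_ else fe / fo
  }, numeric(1))
  setNames(ratios, paste0("L", lengths))
}

branch_fit <- function(periods, freqs) {
  lf <- log(freqs)
  fit_exp <- lm(lf ~ periods)
  fit_pow <- lm(lf ~ log(periods))
  list(exponential_rate = -unname(coef(fit_exp)[2]),
       powerlaw_slope = -unname(coef(fit_pow)[2]),
       rss_exponential = sum(resid(fit_exp)^2),
       rss_powerlaw = sum(resid(fit_pow)^2),
       n_points = length(periods))
}

#' Fit decay laws to a cycle-length distribution
#'
#' Least-squares fits of log-frequency against period (exponential decay,
#' `f(L) ~ exp(-rate * L)`) and against log-period (power law,
#' `f(L) ~ L^-slope`), with residual sums for model comparison. Fixed points
#' (period 1) are excluded: these are cycle-length laws. On the `pm1` map
#' the even and odd branches are fitted separately, since even cycles sit on
#' a systematically higher curve.
#'
#' @param dist a `period_distribution`.
#' @param min_support minimum number of distinct periods with nonzero counts
#'   required per fitted branch.
#' @return a list of branch fits (`all` for the `zero_one` map; `even` and
#'   `odd` for `pm1`), each with `exponential_rate`, `powerlaw_slope`,
#'   `rss_exponential`, `rss_powerlaw`, `n_points`.
#' @export
fit_decay <- function(dist, min_support = 4L) {
  stopifnot(inherits(dist, "period_distribution"))
  keep <- dist$periods >= 2L & dist$counts > 0L
  periods <- dist$periods[keep]
  freqs <- dist$counts[keep] / dist$total
  branches <-
    if (dist$map == "pm1")
      list(even = periods %% 2L == 0L, odd = periods %% 2L == 1L)
    else
      list(all = rep(TRUE, length(periods)))
  lapply(branches, function(sel) {
    if (sum(sel) < min_support)
      stop(sprintf("decay fit needs >= %d distinct periods per branch, got %d",
                   min_support, sum(sel)), call. = FALSE)
    branch_fit(periods[sel], freqs[sel])
  })
}

#' Transient times to a fixed point, across network sizes
#'
#' Mean and dispersion of the transient (steps before entering the
#' attractor) restricted to fixed-point outcomes, for each ensemble in a
#' size grid. Cells where no fixed point was observed are reported as `NA`
#' rather than failing. These summaries are what calibrate iteration-cap
#' policies for large or dense networks.
#'
#' @param specs list of [ensemble_spec()]s (e.g. one per network size) or of
#'   matrix-generator functions.
#' @param dyn a [dynamics_spec()].
#' @param n_trials trials per ensemble.
#' @param seed master seed; one substream per ensemble.
#' @return data frame with `n_genes`, `k`, `mean_transient`, `sd_transient`,
#'   `n_fixed`, `n_trials`.
#' @export
transient_summary <- function(specs, dyn, n_trials, seed = NULL) {
  if (inherits(specs, "ensemble_spec")) specs <- list(specs)
  if (!is.null(seed)) set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    ens <- specs[[i]]
    trials <- run_trials(ens, dyn, n_trials, seed = sub[i])
    tr <- trials$transient[trials$outcome == "fixed_point"]
    is_spec <- inherits(ens, "ensemble_spec")
    data.frame(n_genes = if (is_spec) ens$n_genes else NA_integer_,
               k = if (is_spec) ens$k else NA_real_,
               mean_transient = if (length(tr)) mean(tr) else NA_real_,
               sd_transient = if (length(tr) > 1) stats::sd(tr) else NA_real_,
               n_fixed = length(tr), n_trials = n_trials)
  })
  do.call(rbind, rows)
}

#' Phenotype discovery curve
#'
#' Samples (matrix, initial state) pairs sequentially and tracks the set of
#' distinct fixed-point expression states ("phenotypes") seen so far, pooled
#' across the sampled matrices. Records the sample index of each new
#' discovery and stops when `target_count` distinct phenotypes have been
#' found or `max_samples` is exhausted (censoring is an outcome, not an
#' error).
#'
#' @inheritParams run_trials
#' @param target_count stop after this many distinct fixed-point states
#'   (`NULL` to run to `max_samples`).
#' @param max_samples sampling budget.
#' @return an object of class `discovery_curve`: data frame `events` with
#'   `sample` and `n_discovered` (one row per discovery), plus
#'   `total_samples`, `censored` (`TRUE` if the target was not reached) and
#'   `n_discovered`.
#' @export
discovery_curve <- function(ens, dyn, target_count = NULL,
                            max_samples = 10000L, seed = NULL) {
  if (dyn$norm != "step")
    stop("discovery curves need discrete dynamics", call. = FALSE)
  gen <- ensemble_generator(ens)
  if (is.null(seed) && inherits(ens, "ensemble_spec")) seed <- ens$seed
  if (!is.null(seed)) set.seed(seed)
  quenched <- dyn$zero_convention == "quenched_random"
  seen <- new.env(hash = TRUE, parent = emptyenv())
  ev_sample <- integer(0)
  found <- 0L
  i <- 0L
  while (i < max_samples) {
    i <- i + 1L
    w <- gen()
    if (quenched && is.null(attr(w, "tie_signs"))) w <- with_tie_signs(w)
    x0 <- random_initial_state(nrow(w), dyn$map)
    res <- iterate_to_attractor(w, x0, dyn, keep_attractor = TRUE)
    if (res$outcome != "fixed_point") next
    key <- paste(res$attractor[1L, ], collapse = ",")
    if (!exists(key, envir = seen, inherits = FALSE)) {
      assign(key, TRUE, envir = seen)
      found <- found + 1L
      ev_sample <- c(ev_sample, i)
      if (!is.null(target_count) && found >= target_count) break
    }
  }
  structure(
    list(events = data.frame(sample = ev_sample,
                             n_discovered = seq_along(ev_sample)),
         total_samples = i,
         censored = !is.null(target_count) && found < target_count,
         n_discovered = found),
    class = "discovery_curve")
}

#' @export
print.discovery_curve <- function(x, ...) {
  cat(sprintf("<discovery_curve> %d phenotypes in %d samples%s\n",
              x$n_discovered, x$total_samples,
              if (x$censored) " (censored)" else ""))
  invisible(x)
}
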