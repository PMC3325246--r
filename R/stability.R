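#' Run independent (matrix, initial state) trials
#'
#' Draws `n_trials` independent pairs of a random interaction matrix and a
#' uniform random initial state -- one fresh state per fresh matrix -- and
#' iterates each to its attractor. This is the sampling scheme behind every
#' Monte Carlo quantity in the package.
#'
#' @param ens an [ensemble_spec()], or a function taking no arguments and
#'   returning an interaction matrix (for degenerate or custom ensembles).
#' @param dyn a [dynamics_spec()].
#' @param n_trials number of pairs.
#' @param seed optional integer seed (falls back to `ens$seed`, then to the
#'   current RNG state).
#' @param keep_fixed_states also return the fixed-point state reached by each
#'   stable trial (used by discovery curves).
#' @return data frame with one row per trial: `outcome`, `period`,
#'   `transient`, `steps_run`, and (optionally) a `state` list column.
#' @export
run_trials <- function(ens, dyn, n_trials, seed = NULL,
                       keep_fixed_states = FALSE) {
  stopifnot(inherits(dyn, "dynamics_spec"))
  gen <- ensemble_generator(ens)
  if (is.null(seed) && inherits(ens, "ensemble_spec")) seed <- ens$seed
  if (!is.null(seed)) set.seed(seed)
  quenched <- dyn$zero_convention == "quenched_random"
  outcome <- character(n_trials)
  period <- integer(n_trials)
  transient <- integer(n_trials)
  steps <- integer(n_trials)
  states <- if (keep_fixed_states) vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    w <- gen()
    if (quenched && is.null(attr(w, "tie_signs"))) w <- with_tie_signs(w)
    x0 <- random_initial_state(nrow(w), dyn$map)
    res <- iterate_to_attractor(w, x0, dyn, keep_attractor = keep_fixed_states)
    outcome[i] <- res$outcome
    period[i] <- if (is.na(res$period)) NA_integer_ else res$period
    transient[i] <- if (is.na(res$transient)) NA_integer_ else res$transient
    steps[i] <- res$steps_run
    if (keep_fixed_states && res$outcome == "fixed_point")
      states[[i]] <- res$attractor[1L, ]
  }
  out <- data.frame(outcome = outcome, period = period,
                    transient = transient, steps_run = steps)
  if (keep_fixed_states) out$state <- states
  out
}

# normalize an ensemble argument to a zero-argument matrix generator
ensemble_generator <- function(ens) {
  if (is.function(ens)) return(ens)
  stopifnot(inherits(ens, "ensemble_spec"))
  function() generate_matrix(ens)
}

new_stability_estimate <- function(omega, f, cycles, unresolved,
                                   exact = FALSE, per_matrix = NULL,
                                   provenance = NULL) {
  s <- f / omega
  structure(
    list(omega = omega, f = f, cycles = cycles, unresolved = unresolved,
         s = s,
         se = if (exact) 0 else sqrt(s * (1 - s) / omega),
         exact = exact, per_matrix = per_matrix, provenance = provenance),
    class = "stability_estimate")
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf("<stability_estimate> S = %.4f", x$s))
  if (x$exact) cat(" (exact)")
  else cat(sprintf(" +/- %.4f (binomial se)", x$se))
  cat(sprintf("\n  omega = %d trials: %d fixed points, %d cycles, %d unresolved\n",
              x$omega, x$f, x$cycles, x$unresolved))
  invisible(x)
}

#' Estimate stability by Monte Carlo
#'
#' Stability is `S = F / Omega`: the fraction of `Omega` independent
#' (matrix, initial state) pairs whose attractor is a fixed point. `1 - S`
#' estimates the probability of reaching a limit cycle. Runs censored at
#' `t_max` are counted as non-fixed-point by default (they are reported
#' separately and never silently dropped); `unresolved = "drop"` removes
#' them from `Omega` instead.
#'
#' @inheritParams run_trials
#' @param unresolved accounting for censored runs: `"count_nonfixed"`
#'   (default) or `"drop"`.
#' @return a `stability_estimate`: counts (`omega`, `f`, `cycles`,
#'   `unresolved`), the estimate `s`, and its binomial (Wald) standard error
#'   `se`. Use [stability_ci()] for an exact interval near 0 or 1.
#' @examples
#' ens <- ensemble_spec(5, k = 5, seed = 1)
#' estimate_stability(ens, dynamics_spec("pm1"), 200)
#' @export
estimate_stability <- function(ens, dyn, n_trials, seed = NULL,
                               unresolved = c("count_nonfixed", "drop")) {
  unresolved <- match.arg(unresolved)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  trials <- run_trials(ens, dyn, n_trials, seed)
  f <- sum(trials$outcome == "fixed_point")
  cyc <- sum(trials$outcome == "cycle")
  unres <- sum(trials$outcome == "unresolved")
  omega <- if (unresolved == "drop") n_trials - unres else n_trials
  new_stability_estimate(omega, f, cyc, unres,
                         provenance = list(ens = ens, dyn = dyn, seed = seed,
                                           unresolved = unresolved))
}

#' Confidence interval for a stability estimate
#'
#' @param est a `stability_estimate`.
#' @param level confidence level.
#' @param method `"wald"` (normal approximation) or `"exact"`
#'   (Clopper-Pearson, preferred when S is near 0 or 1).
#' @return length-2 numeric vector (lower, upper).
#' @export
stability_ci <- function(est, level = 0.95, method = c("wald", "exact")) {
  method <- match.arg(method)
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- est$s + c(-1, 1) * z * est$se
    pmin(pmax(ci, 0), 1)
  } else {
    as.numeric(stats::binom.test(est$f, est$omega,
                                 conf.level = level)$conf.int)
  }
}

#' Fraction of initial states that reach a fixed point, for one matrix
#'
#' @param w interaction matrix.
#' @param dyn a [dynamics_spec()].
#' @param states `"all"` (enumerate the full `2^N` state space; guarded) or
#'   an integer number of uniform random initial states.
#' @param max_states enumeration guard for `states = "all"`.
#' @return list with `fraction`, `trials`, `exact` (full enumeration flag)
#'   and `unresolved`.
#' @export
matrix_stability <- function(w, dyn, states = "all", max_states = 2^16) {
  n <- nrow(w)
  if (identical(states, "all")) {
    xs <- enumerate_states(n, dyn$map, max_states = max_states)
    exact <- TRUE
  } else {
    xs <- t(vapply(seq_len(states),
                   function(i) random_initial_state(n, dyn$map),
                   integer(n)))
    exact <- FALSE
  }
  fixed <- 0L; unres <- 0L
  for (r in seq_len(nrow(xs))) {
    res <- iterate_to_attractor(w, xs[r, ], dyn)
    if (res$outcome == "fixed_point") fixed <- fixed + 1L
    else if (res$outcome == "unresolved") unres <- unres + 1L
  }
  list(fraction = fixed / nrow(xs), trials = nrow(xs), exact = exact,
       unresolved = unres)
}

#' Exact stability by full enumeration
#'
#' Enumerates every binary regular matrix (exactly `k` +/-1 entries per row)
#' and every initial state, iterates each pair to its attractor, and returns
#' the exact stability together with the per-matrix stability vector. With
#' the discrete step norm and `t_max` at its default, every pair resolves,
#' so `S` is exact and its standard error is zero.
#'
#' @param n number of genes.
#' @param k inputs per gene.
#' @param dyn a [dynamics_spec()].
#' @param allow_self_loops permit diagonal entries.
#' @param max_pairs guard on `(#matrices) * 2^n`.
#' @return a `stability_estimate` with `exact = TRUE` and a `per_matrix`
#'   vector of per-matrix fixed-point fractions.
#' @examples
#' exact_stability(1, 1, dynamics_spec("pm1"))$s  # 0.5
#' @export
exact_stability <- function(n, k, dyn = dynamics_spec(),
                            allow_self_loops = TRUE, max_pairs = 2^22) {
  en <- enumerate_binary_matrices(n, k, allow_self_loops,
                                  max_matrices = max_pairs)
  n_pairs <- en$count * 2^n
  if (n_pairs > max_pairs)
    stop(sprintf("enumeration needs %s (matrix, state) pairs, above the guard of %s",
                 format(n_pairs, big.mark = ","),
                 format(max_pairs, big.mark = ",")), call. = FALSE)
  xs <- enumerate_states(n, dyn$map)
  per_matrix <- numeric(en$count)
  f <- 0L; cyc <- 0L; unres <- 0L
  m <- 0L
  while (!is.null(w <- en$nxt())) {
    m <- m + 1L
    fixed_m <- 0L
    for (r in seq_len(nrow(xs))) {
      res <- iterate_to_attractor(w, xs[r, ], dyn)
      if (res$outcome == "fixed_point") fixed_m <- fixed_m + 1L
      else if (res$outcome == "cycle") cyc <- cyc + 1L
      else unres <- unres + 1L
    }
    f <- f + fixed_m
    per_matrix[m] <- fixed_m / nrow(xs)
  }
  new_stability_estimate(as.integer(n_pairs), f, cyc, unres, exact = TRUE,
                         per_matrix = per_matrix,
                         provenance = list(n = n, k = k, dyn = dyn))
}

#' Per-matrix stability distribution
#'
#' Computes each matrix's fixed-point fraction over initial states and bins
#' the fractions. Matrices that are never stable (fraction exactly 0) and
#' always stable (exactly 1) are tallied separately in addition to the
#' histogram, since the distribution's bimodality -- most matrices at 0, a
#' smaller stable class at 1 -- is its headline feature.
#'
#' @param matrices a list of interaction matrices, or a `matrix_enumerator`
#'   from [enumerate_binary_matrices()].
#' @param dyn a [dynamics_spec()].
#' @param states per-matrix initial states: `"all"` or a sample size (see
#'   [matrix_stability()]).
#' @param bins number of equal-width histogram bins on `[0, 1]` (default 20,
#'   i.e. width 0.05).
#' @return an object of class `stability_histogram`: `fractions`
#'   (per-matrix values), `counts`, `breaks`, `n_exact_zero`, `n_exact_one`.
#' @export
matrix_stability_distribution <- function(matrices, dyn, states = "all",
                                          bins = 20L) {
  fractions <-
    if (inherits(matrices, "matrix_enumerator")) {
      matrices$reset()
      out <- numeric(0)
      while (!is.null(w <- matrices$nxt()))
        out <- c(out, matrix_stability(w, dyn, states)$fraction)
      out
    } else {
      vapply(matrices, function(w) matrix_stability(w, dyn, states)$fraction,
             numeric(1))
    }
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(fractions, breaks,
                                       rightmost.closed = TRUE), bins),
                     nbins = bins)
  structure(
    list(fractions = fractions, counts = counts, breaks = breaks,
         n_exact_zero = sum(fractions == 0),
         n_exact_one = sum(fractions == 1)),
    class = "stability_histogram")
}

#' @export
print.stability_histogram <- function(x, ...) {
  cat(sprintf("<stability_histogram> %d matrices: %d never stable, %d always stable\n",
              length(x$fractions), x$n_exact_zero, x$n_exact_one))
  invisible(x)
}

sweep_axes <- c("N", "c_or_K", "map", "weight_scheme", "steepness",
                "topology", "zero_convention")

apply_axis <- function(axis, value, ens, dyn) {
  switch(axis,
    N = {
      if (ens$conn_mode == "density")
        ens <- ensemble_spec(value, density = ens$density,
                             topology = ens$topology,
                             weight_scheme = ens$weight_scheme,
                             allow_self_loops = ens$allow_self_loops)
      else
        ens <- ensemble_spec(value, k = ens$k, topology = ens$topology,
                             weight_scheme = ens$weight_scheme,
                             allow_self_loops = ens$allow_self_loops)
    },
    c_or_K = {
      if (value <= 1)
        ens <- ensemble_spec(ens$n_genes, density = value,
                             topology = ens$topology,
                             weight_scheme = ens$weight_scheme,
                             allow_self_loops = ens$allow_self_loops)
      else
        ens <- ensemble_spec(ens$n_genes, k = value, topology = ens$topology,
                             weight_scheme = ens$weight_scheme,
                             allow_self_loops = ens$allow_self_loops)
    },
    weight_scheme = {
      ens <- ensemble_spec(ens$n_genes, k = ens$k, topology = ens$topology,
                           weight_scheme = value,
                           allow_self_loops = ens$allow_self_loops)
    },
    topology = {
      ens <- ensemble_spec(ens$n_genes, k = ens$k, topology = value,
                           weight_scheme = ens$weight_scheme,
                           allow_self_loops = ens$allow_self_loops)
    },
    map = dyn$map <- match.arg(value, c("pm1", "zero_one")),
    steepness = {
      dyn <- dynamics_spec(dyn$map, norm = "sigmoid", steepness = value,
                           zero_convention = dyn$zero_convention,
                           t_max = dyn$t_max, eps = dyn$eps,
                           window = dyn$window)
    },
    zero_convention = dyn$zero_convention <-
      match.arg(value, names(ZERO_CONV_CODES)))
  list(ens = ens, dyn = dyn)
}

#' Sweep stability along one model axis
#'
#' Re-estimates stability at each grid point of a single swept parameter,
#' holding the base ensemble and dynamics fixed otherwise. Each grid point
#' runs on its own seed substream spawned from `seed`, so the whole table is
#' reproducible and points are independent.
#'
#' @param axis one of `"N"`, `"c_or_K"` (values <= 1 are densities, larger
#'   values in-degrees), `"map"`, `"weight_scheme"`, `"steepness"`,
#'   `"topology"`, `"zero_convention"`.
#' @param grid vector of axis values (nonempty).
#' @param base_ens base [ensemble_spec()]. When `axis = "N"`, connectivity
#'   scales with N if the base spec was given as a density, and stays fixed
#'   if it was given as `k`.
#' @param base_dyn base [dynamics_spec()].
#' @param n_trials trials per grid point.
#' @param seed master seed for the sweep.
#' @return data frame with columns `axis`, `value`, `s`, `se`, `omega`,
#'   `f`, `cycles`, `unresolved`, `seed`.
#' @examples
#' sweep_stability("N", c(4, 6), ensemble_spec(4, density = 1),
#'                 dynamics_spec("pm1"), n_trials = 100, seed = 1)
#' @export
sweep_stability <- function(axis, grid, base_ens, base_dyn, n_trials,
                            seed = NULL) {
  axis <- match.arg(axis, sweep_axes)
  if (length(grid) == 0) stop("`grid` must be nonempty", call. = FALSE)
  if (is.null(seed)) seed <- base_ens$seed
  if (!is.null(seed)) set.seed(seed)
  pt_seeds <- sample.int(.Machine$integer.max - 1L, length(grid))
  rows <- lapply(seq_along(grid), function(i) {
    mod <- apply_axis(axis, grid[[i]], base_ens, base_dyn)
    est <- estimate_stability(mod$ens, mod$dyn, n_trials, seed = pt_seeds[i])
    data.frame(axis = axis, value = as.character(grid[[i]]),
               s = est$s, se = est$se, omega = est$omega, f = est$f,
               cycles = est$cycles, unresolved = est$unresolved,
               seed = pt_seeds[i])
  })
  do.call(rbind, rows)
}

#' @rdname sweep_stability
#' @param tab a sweep table.
#' @param path output TSV file.
#' @export
write_sweep <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
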