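#' Draw a random interaction matrix from an ensemble
#'
#' Generates one N x N signed interaction matrix `W` according to the
#' ensemble's topology and weight scheme. `w[i, j]` is the regulatory effect
#' of gene j on gene i; a zero entry means no interaction, and diagonal
#' entries represent self-regulation. Matrices are generally not symmetric.
#' Draws use the current R random number generator state, so a `set.seed()`
#' call before generation makes the draw reproducible.
#'
#' Topologies:
#' * `regular` -- every gene has exactly `k` inputs at uniformly chosen
#'   positions.
#' * `poisson` -- per-gene in-degrees are Poisson with mean `k`, truncated to
#'   the feasible range; genes with in-degree 0 are legal (their update is
#'   governed by the zero-input convention of the dynamics).
#' * `bio_exp_in_pow_out` -- in-degrees follow a discretized exponential with
#'   mean `k`; each gene's inputs are then chosen with probabilities
#'   proportional to per-gene power-law propensities whose mean is solved to
#'   equal `k`, giving a heavy-tailed out-degree distribution as observed in
#'   transcriptional regulatory networks.
#'
#' @param spec an [ensemble_spec()].
#' @return numeric N x N matrix with attributes `topology` and
#'   `weight_scheme`.
#' @examples
#' set.seed(1)
#' w <- generate_matrix(ensemble_spec(10, k = 2))
#' rowSums(w != 0)  # exactly 2 inputs per gene
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  w <- switch(spec$topology,
    regular = gen_regular(spec),
    poisson = gen_poisson(spec),
    bio_exp_in_pow_out = gen_biological(spec))
  attr(w, "topology") <- spec$topology
  attr(w, "weight_scheme") <- spec$weight_scheme
  w
}

#' Draw a reproducible batch of matrices
#'
#' Seeds the generator from `spec$seed` (when present) and draws `n_draws`
#' matrices sequentially, so the same spec always yields the same batch.
#'
#' @param spec an [ensemble_spec()].
#' @param n_draws number of matrices.
#' @return list of matrices.
#' @export
generate_ensemble <- function(spec, n_draws) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  lapply(seq_len(n_draws), function(i) generate_matrix(spec))
}

# sample `size` values from `x` (a vector, never scalar-expanded)
sample_vec <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

draw_weights <- function(n, scheme) {
  if (scheme == "binary_pm1") {
    sample(c(-1, 1), n, replace = TRUE)
  } else {
    w <- rnorm(n)
    while (any(w == 0)) w[w == 0] <- rnorm(sum(w == 0))  # measure-zero guard
    w
  }
}

gen_regular <- function(spec) {
  n <- spec$n_genes; k <- as.integer(spec$k)
  if (!spec$allow_self_loops && k > n - 1L)
    stop("regular topology without self-loops needs k <= n_genes - 1",
         call. = FALSE)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pool <- if (spec$allow_self_loops) seq_len(n) else seq_len(n)[-i]
    cols <- sample_vec(pool, k)
    w[i, cols] <- draw_weights(k, spec$weight_scheme)
  }
  w
}

gen_poisson <- function(spec) {
  n <- spec$n_genes
  dmax <- if (spec$allow_self_loops) n else n - 1L
  deg <- rpois(n, spec$k)
  while (any(deg > dmax)) deg[deg > dmax] <- rpois(sum(deg > dmax), spec$k)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (deg[i] == 0L) next
    pool <- if (spec$allow_self_loops) seq_len(n) else seq_len(n)[-i]
    cols <- sample_vec(pool, deg[i])
    w[i, cols] <- draw_weights(deg[i], spec$weight_scheme)
  }
  w
}

# mean of the discretized exponential P(d) proportional to q^d, d = 0..n
trunc_geom_mean <- function(q, n) {
  d <- 0:n
  p <- q^d
  sum(d * p) / sum(p)
}

# mean of the discrete power law P(d) proportional to d^(-gamma), d = 1..n
trunc_powerlaw_mean <- function(gamma, n) {
  d <- seq_len(n)
  p <- d^(-gamma)
  sum(d * p) / sum(p)
}

# solve the power-law exponent so the truncated mean equals k; bisection on
# (1.5, 4) by default, widened when the target lies outside that bracket.
# Means below the steep-exponent limit (just above 1) clamp to the steepest
# exponent; means above the shallow limit are infeasible.
solve_powerlaw_exponent <- function(k, n, lo = 1.5, hi = 4) {
  f <- function(g) trunc_powerlaw_mean(g, n) - k
  if (f(lo) < 0) lo <- 1.01
  if (f(hi) > 0) hi <- 50
  if (f(lo) < 0)
    stop(sprintf(
      "mean out-degree %.3g is not attainable by a truncated power law on 1..%d",
      k, n), call. = FALSE)
  if (f(hi) >= 0) return(hi)
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

gen_biological <- function(spec) {
  n <- spec$n_genes; k <- spec$k
  if (k > n / 2 + 1e-9)
    stop(sprintf(
      paste("bio_exp_in_pow_out: mean in-degree k = %.3g is not attainable by",
            "a truncated exponential on 0..%d (its mean cannot exceed %d/2)"),
      k, n, n), call. = FALSE)
  # in-degrees: discretized exponential with mean k, support 0..n; the
  # flat-distribution limit covers k exactly at n/2
  pin <- if (k >= n / 2 - 1e-9) rep(1, n + 1) else {
    q <- uniroot(function(q) trunc_geom_mean(q, n) - k,
                 c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    q^(0:n)
  }
  deg <- sample(0:n, n, replace = TRUE, prob = pin)
  # out-degree propensities: discrete power law on 1..n with mean k
  gamma <- solve_powerlaw_exponent(k, n)
  pout <- seq_len(n)^(-gamma)
  prop <- sample(seq_len(n), n, replace = TRUE, prob = pout / sum(pout))
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (deg[i] == 0L) next
    pool <- if (spec$allow_self_loops) seq_len(n) else seq_len(n)[-i]
    d <- min(deg[i], length(pool))
    cols <- sample_vec(pool, d, prob = prop[pool])
    w[i, cols] <- draw_weights(d, spec$weight_scheme)
  }
  w
}

#' Draw or enumerate initial expression states
#'
#' States are length-N vectors over `{-1, +1}` (the `pm1` map) or `{0, 1}`
#' (the `zero_one` map). `random_initial_state` draws uniformly over the
#' `2^N` discrete states; `enumerate_states` lists all of them, refusing when
#' `2^N` exceeds `max_states`.
#'
#' @param n number of genes.
#' @param map `"pm1"` or `"zero_one"`.
#' @param max_states enumeration guard.
#' @return `random_initial_state`: integer vector of length `n`.
#'   `enumerate_states`: integer matrix with `2^n` rows, one state per row.
#' @examples
#' enumerate_states(2, "pm1")
#' @export
random_initial_state <- function(n, map = c("pm1", "zero_one")) {
  map <- match.arg(map)
  vals <- if (map == "pm1") c(-1L, 1L) else c(0L, 1L)
  sample(vals, n, replace = TRUE)
}

#' @rdname random_initial_state
#' @export
enumerate_states <- function(n, map = c("pm1", "zero_one"),
                             max_states = 2^20) {
  map <- match.arg(map)
  count <- 2^n
  if (count > max_states)
    stop(sprintf("state space has %s states, above the guard of %s",
                 format(count, big.mark = ","),
                 format(max_states, big.mark = ",")), call. = FALSE)
  off <- if (map == "pm1") -1L else 0L
  bits <- as.matrix(expand.grid(rep(list(c(off, 1L)), n)))
  dimnames(bits) <- NULL
  storage.mode(bits) <- "integer"
  bits
}

#' Enumerate every binary regular interaction matrix
#'
#' Iterates over all N x N matrices with exactly `k` nonzero entries per row,
#' each entry +/-1, visiting each matrix exactly once. The space has
#' `(choose(N, k) * 2^k)^N` members, so enumeration is guarded by
#' `max_matrices`.
#'
#' @param n number of genes.
#' @param k inputs per gene.
#' @param allow_self_loops permit diagonal entries.
#' @param max_matrices refuse enumeration above this count.
#' @return an iterator of class `matrix_enumerator`: call `$nxt()` for the
#'   next matrix (or `NULL` when exhausted), `$reset()` to restart; `$count`
#'   holds the total number of matrices.
#' @examples
#' en <- enumerate_binary_matrices(2, 1)
#' en$count  # 16
#' @export
enumerate_binary_matrices <- function(n, k, allow_self_loops = TRUE,
                                      max_matrices = 2^20) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1L || k > n) stop("need 1 <= k <= n", call. = FALSE)
  npos <- if (allow_self_loops) n else n - 1L
  if (k > npos) stop("k exceeds available positions", call. = FALSE)
  per_row <- choose(npos, k) * 2^k
  total <- per_row^n
  if (total > max_matrices)
    stop(sprintf("matrix space has %s members, above the guard of %s",
                 format(total, big.mark = ","),
                 format(max_matrices, big.mark = ",")), call. = FALSE)
  # all realizations of one row, as a (per_row x n) matrix, per gene
  row_opts <- lapply(seq_len(n), function(i) {
    pool <- if (allow_self_loops) seq_len(n) else seq_len(n)[-i]
    pos <- utils::combn(pool, k)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    out <- matrix(0, ncol(pos) * nrow(signs), n)
    r <- 0L
    for (p in seq_len(ncol(pos))) for (s in seq_len(nrow(signs))) {
      r <- r + 1L
      out[r, pos[, p]] <- signs[s, ]
    }
    out
  })
  idx <- rep(1L, n)  # mixed-radix counter, one digit per gene row
  done <- FALSE
  nxt <- function() {
    if (done) return(NULL)
    w <- t(vapply(seq_len(n), function(i) row_opts[[i]][idx[i], ],
                  numeric(n)))
    i <- n
    repeat {
      if (i == 0L) { done <<- TRUE; break }
      if (idx[i] < nrow(row_opts[[i]])) { idx[i] <<- idx[i] + 1L; break }
      idx[i] <<- 1L; i <- i - 1L
    }
    w
  }
  reset <- function() { idx <<- rep(1L, n); done <<- FALSE; invisible(NULL) }
  structure(list(count = total, nxt = nxt, reset = reset, n = n, k = k),
            class = "matrix_enumerator")
}

#' @export
print.matrix_enumerator <- function(x, ...) {
  cat(sprintf("<matrix_enumerator> N = %d, k = %d, %s matrices\n",
              x$n, x$k, format(x$count, big.mark = ",")))
  invisible(x)
}
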