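ZERO_CONV_CODES <- c(minus = 0L, plus = 1L, keep_previous = 2L,
                     quenched_random = 3L)
OUTCOME_LEVELS <- c("fixed_point", "cycle", "unresolved")

#' Specify the update dynamics
#'
#' The dynamics are the synchronous deterministic map
#' `x(t+1) = sigma(W x(t))`: every gene's net input `h_i = sum_j w_ij x_j` is
#' computed from the same state and passed through the normalization `sigma`.
#' With `norm = "step"` the state stays on the discrete map (`sign(h)` for
#' `pm1`, Heaviside for `zero_one`), and `sigma(0)` is resolved by
#' `zero_convention`. With `norm = "sigmoid"` the state is continuous:
#' `sigma(h) = 2 / (1 + exp(-a h)) - 1` on the `pm1` map and
#' `sigma(h) = 1 / (1 + exp(-a h))` on the `zero_one` map, both of which
#' converge to the step function as the steepness `a` grows.
#'
#' @param map `"pm1"` (off state is -1) or `"zero_one"` (off state is 0).
#' @param norm `"step"` (discrete states) or `"sigmoid"` (continuous).
#' @param steepness sigmoid steepness `a > 0`; ignored for the step norm.
#' @param zero_convention resolution of a zero net input under the step
#'   norm: `"minus"` (off state, the default), `"plus"` (on state),
#'   `"keep_previous"` (gene keeps its state), or `"quenched_random"` (a
#'   per-gene tie-break sign fixed once per matrix, keeping the dynamics
#'   deterministic).
#' @param t_max iteration cap; `NULL` uses
#'   `min(2^N + 1, max(1e4, 100 N))` for discrete runs and
#'   `max(1e4, 100 N)` for continuous runs.
#' @param eps continuous-case convergence tolerance (max-norm).
#' @param window consecutive small-change steps required to declare a
#'   continuous fixed point.
#' @return an object of class `dynamics_spec`.
#' @examples
#' dynamics_spec("pm1")
#' dynamics_spec("zero_one", norm = "sigmoid", steepness = 100)
#' @export
dynamics_spec <- function(map = c("pm1", "zero_one"),
                          norm = c("step", "sigmoid"),
                          steepness = NULL,
                          zero_convention = c("minus", "plus",
                                              "keep_previous",
                                              "quenched_random"),
                          t_max = NULL, eps = 1e-6, window = 10L) {
  map <- match.arg(map)
  norm <- match.arg(norm)
  zero_convention <- match.arg(zero_convention)
  if (norm == "sigmoid") {
    if (is.null(steepness) || !is.numeric(steepness) || steepness <= 0)
      stop("sigmoid norm needs a positive `steepness`", call. = FALSE)
  }
  if (!is.null(t_max) && (t_max < 1 || t_max != round(t_max)))
    stop("`t_max` must be a positive integer", call. = FALSE)
  if (eps <= 0) stop("`eps` must be positive", call. = FALSE)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  structure(
    list(map = map, norm = norm, steepness = steepness,
         zero_convention = zero_convention,
         t_max = if (is.null(t_max)) NULL else as.integer(t_max),
         eps = eps, window = as.integer(window)),
    class = "dynamics_spec")
}

#' @export
print.dynamics_spec <- function(x, ...) {
  cat("<dynamics_spec>\n")
  cat(sprintf("  map = %s, norm = %s%s\n", x$map, x$norm,
              if (x$norm == "sigmoid")
                sprintf(" (steepness a = %g)", x$steepness) else ""))
  cat(sprintf("  sigma(0) -> %s, t_max = %s\n", x$zero_convention,
              if (is.null(x$t_max)) "auto" else x$t_max))
  invisible(x)
}

map_on_off <- function(map) {
  if (map == "pm1") c(on = 1L, off = -1L) else c(on = 1L, off = 0L)
}

# iteration cap policy; the discrete cap 2^N + 1 guarantees exact resolution
# whenever the full state space fits under it
resolve_t_max <- function(spec, n) {
  if (!is.null(spec$t_max)) return(spec$t_max)
  base <- max(10000, 100 * n)
  if (spec$norm == "step" && n < 31) min(2^n + 1, base) else base
}

# per-gene quenched tie-break signs: stored on the matrix if present,
# otherwise drawn once (from the current RNG) per call
resolve_tie_signs <- function(w, spec) {
  n <- nrow(w)
  if (spec$zero_convention != "quenched_random") return(rep(1L, n))
  ts <- attr(w, "tie_signs")
  if (is.null(ts)) ts <- sample(c(-1L, 1L), n, replace = TRUE)
  as.integer(ts)
}

#' Attach quenched tie-break signs to a matrix
#'
#' Under the `quenched_random` zero-input convention each gene resolves a
#' zero net input with a fixed random sign drawn once at matrix creation, so
#' the dynamics remain deterministic and exact cycle detection stays valid.
#'
#' @param w interaction matrix.
#' @return `w` with a `tie_signs` attribute.
#' @export
with_tie_signs <- function(w) {
  attr(w, "tie_signs") <- sample(c(-1L, 1L), nrow(w), replace = TRUE)
  w
}

check_state <- function(w, x, spec) {
  if (length(x) != nrow(w) || nrow(w) != ncol(w))
    stop("dimension mismatch between matrix and state", call. = FALSE)
  oo <- map_on_off(spec$map)
  if (spec$norm == "step" && !all(x %in% c(oo["on"], oo["off"]))) {
    mid <- if (spec$map == "pm1") 0 else 0.5
    warning("continuous state coerced to the discrete map by thresholding",
            call. = FALSE)
    x <- ifelse(x > mid, oo[["on"]], oo[["off"]])
  }
  x
}

#' One synchronous update
#'
#' Applies `x(t+1) = sigma(W x(t))` once: every gene is updated
#' simultaneously from the same input state.
#'
#' @param w interaction matrix.
#' @param x state vector conforming to `spec$map`.
#' @param spec a [dynamics_spec()].
#' @return the next state (integer vector for the step norm, numeric for the
#'   sigmoid norm).
#' @examples
#' w <- diag(2)
#' rtn_step(w, c(1, -1), dynamics_spec("pm1"))
#' @export
rtn_step <- function(w, x, spec = dynamics_spec()) {
  x <- check_state(w, x, spec)
  oo <- map_on_off(spec$map)
  if (spec$norm == "step") {
    cpp_step_discrete(w, as.integer(x), oo[["on"]], oo[["off"]],
                      ZERO_CONV_CODES[[spec$zero_convention]],
                      resolve_tie_signs(w, spec))
  } else {
    cpp_step_continuous(w, as.numeric(x), spec$steepness, spec$map == "pm1")
  }
}

#' Iterate the dynamics to an attractor
#'
#' Runs the synchronous dynamics from `x0` until the attractor is found or
#' `t_max` is exhausted. In the discrete (step) case every visited state is
#' hashed and the first revisit yields the exact transient and period, so the
#' result is exact whenever `t_max >= transient + period`. In the continuous
#' (sigmoid) case a fixed point is declared when the max-norm step change
#' stays below `eps` for `window` consecutive steps, and a cycle when a
#' checkpoint state (stored at powers of two) recurs within `eps`. Runs that
#' do not resolve within `t_max` are reported as `"unresolved"`, never
#' silently classified.
#'
#' @inheritParams rtn_step
#' @param x0 initial state.
#' @param keep_attractor retain the attractor's state sequence (discrete
#'   case) or final state (continuous case).
#' @return an object of class `trajectory_result`: list with `outcome`
#'   (`"fixed_point"`, `"cycle"` or `"unresolved"`), `period` (1 for fixed
#'   points, `NA` if unresolved), `transient` (steps before entering the
#'   attractor), `steps_run`, and optionally `attractor` (a period x N
#'   matrix of attractor states).
#' @examples
#' w <- -diag(3)  # every state flips: a 2-cycle
#' iterate_to_attractor(w, c(1, 1, -1), dynamics_spec("pm1"))
#' @export
iterate_to_attractor <- function(w, x0, spec = dynamics_spec(),
                                 keep_attractor = FALSE) {
  x0 <- check_state(w, x0, spec)
  n <- nrow(w)
  t_max <- resolve_t_max(spec, n)
  if (spec$norm == "step") {
    oo <- map_on_off(spec$map)
    raw <- cpp_iterate_discrete(w, as.integer(x0), oo[["on"]], oo[["off"]],
                                ZERO_CONV_CODES[[spec$zero_convention]],
                                resolve_tie_signs(w, spec), t_max,
                                keep_attractor)
  } else {
    raw <- cpp_iterate_continuous(w, as.numeric(x0), spec$steepness,
                                  spec$map == "pm1", t_max, spec$eps,
                                  spec$window)
    if (keep_attractor && raw$outcome != 2L)
      raw$attractor <- matrix(raw$state, nrow = 1)
  }
  unresolved <- raw$outcome == 2L
  structure(
    list(outcome = OUTCOME_LEVELS[raw$outcome + 1L],
         period = if (unresolved) NA_integer_ else raw$period,
         transient = if (unresolved) NA_integer_ else raw$transient,
         steps_run = raw$steps_run,
         attractor = raw$attractor),
    class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat(sprintf("<trajectory_result> %s", x$outcome))
  if (!is.na(x$period))
    cat(sprintf(" (period %d, transient %d)", x$period, x$transient))
  cat(sprintf(", %d steps run\n", x$steps_run))
  invisible(x)
}

#' Serialize a trajectory result as JSON
#'
#' @param res a `trajectory_result`.
#' @return a JSON string.
#' @export
trajectory_to_json <- function(res) {
  stopifnot(inherits(res, "trajectory_result"))
  rec <- res[c("outcome", "period", "transient", "steps_run")]
  if (!is.null(res$attractor)) rec$attractor <- unclass(res$attractor)
  jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
}

#' Record a trajectory in long form
#'
#' Runs `steps` synchronous updates and returns the visited states as a tidy
#' (time, gene, value) table, suitable for TSV export with
#' [write_trajectory()].
#'
#' @inheritParams rtn_step
#' @param x0 initial state.
#' @param steps number of updates to record.
#' @return data frame with columns `time` (0-based), `gene`, `value`.
#' @export
simulate_trajectory <- function(w, x0, spec = dynamics_spec(), steps = 20L) {
  x <- check_state(w, x0, spec)
  n <- nrow(w)
  out <- matrix(NA_real_, steps + 1L, n)
  out[1L, ] <- x
  for (t in seq_len(steps)) {
    x <- rtn_step(w, x, spec)
    out[t + 1L, ] <- x
  }
  data.frame(time = rep(0:steps, each = n),
             gene = rep(seq_len(n), steps + 1L),
             value = as.vector(t(out)))
}

#' @rdname simulate_trajectory
#' @param traj a trajectory table from `simulate_trajectory`.
#' @param path output TSV file.
#' @export
write_trajectory <- function(traj, path) {
  write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Does a steep sigmoid reproduce the sign dynamics?
#'
#' For binary +/-1 weights on the `pm1` map with odd in-degree K, net inputs
#' are odd integers and never zero, so the sign trajectory is well defined.
#' This compares the continuous sigmoid trajectory (steepness `a`),
#' thresholded by sign, against the exact step trajectory over `horizon`
#' steps from the same initial state.
#'
#' @param w binary +/-1 interaction matrix with an odd number of nonzero
#'   entries in every row.
#' @param x0 initial +/-1 state.
#' @param a sigmoid steepness.
#' @param horizon number of steps to compare.
#' @return `TRUE` if the sign of every sigmoid state component matches the
#'   step trajectory at every step up to `horizon`.
#' @export
sigmoid_matches_sign <- function(w, x0, a, horizon = 100L) {
  if (!all(w %in% c(-1, 0, 1)))
    stop("`w` must have binary +/-1 weights", call. = FALSE)
  deg <- rowSums(w != 0)
  if (any(deg %% 2 == 0))
    stop("every in-degree must be odd (even K allows zero net inputs)",
         call. = FALSE)
  if (!all(x0 %in% c(-1, 1)))
    stop("`x0` must be a +/-1 state", call. = FALSE)
  xd <- as.integer(x0)
  xc <- as.numeric(x0)
  tie <- rep(1L, nrow(w))
  for (t in seq_len(horizon)) {
    xd <- cpp_step_discrete(w, xd, 1L, -1L, ZERO_CONV_CODES[["minus"]], tie)
    xc <- cpp_step_continuous(w, xc, a, TRUE)
    if (any(sign(xc) != xd)) return(FALSE)
  }
  TRUE
}
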