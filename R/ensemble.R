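#' Describe a random-network ensemble
#'
#' An ensemble specification fixes everything needed to draw interaction
#' matrices: the number of genes N, the connectivity (either the in-degree
#' `k` or the density `c = k/N`; give exactly one), the degree topology, the
#' weight scheme, whether self-regulation (diagonal entries) is allowed, and
#' an optional seed.
#'
#' @param n_genes number of genes N (positive integer).
#' @param k in-degree: number of regulatory inputs per gene (mean in-degree
#'   for non-regular topologies). Mutually exclusive with `density`.
#' @param density fraction `c` of nonzero matrix entries, `c = k/N`.
#' @param topology one of `"regular"` (every gene has exactly `k` inputs),
#'   `"poisson"` (in-degrees Poisson with mean `k`), or
#'   `"bio_exp_in_pow_out"` (exponential in-degrees, power-law out-degrees,
#'   both with mean `k`, as observed in transcriptional networks).
#' @param weight_scheme `"binary_pm1"` (nonzero weights are +/-1 with equal
#'   probability) or `"real_gaussian"` (standard normal weights).
#' @param allow_self_loops logical; permit diagonal entries (self-regulation).
#' @param seed optional integer seed recorded in the spec and used by
#'   ensemble-level drivers.
#'
#' @return an object of class `ensemble_spec`.
#' @examples
#' ensemble_spec(10, k = 2)
#' ensemble_spec(100, density = 0.02, topology = "poisson")
#' @export
ensemble_spec <- function(n_genes, k = NULL, density = NULL,
                          topology = c("regular", "poisson",
                                       "bio_exp_in_pow_out"),
                          weight_scheme = c("binary_pm1", "real_gaussian"),
                          allow_self_loops = TRUE, seed = NULL) {
  topology <- match.arg(topology)
  weight_scheme <- match.arg(weight_scheme)
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != round(n_genes))
    stop("`n_genes` must be a positive integer", call. = FALSE)
  n_genes <- as.integer(n_genes)
  if (is.null(k) && is.null(density))
    stop("give one of `k` or `density`", call. = FALSE)
  conn_mode <- if (is.null(k)) "density" else "k"
  if (!is.null(k) && !is.null(density) && abs(density - k / n_genes) > 1e-9)
    stop("`k` and `density` disagree: density must equal k/n_genes",
         call. = FALSE)
  if (is.null(k)) {
    if (density <= 0 || density > 1)
      stop("`density` must lie in (0, 1]", call. = FALSE)
    k <- density * n_genes
    if (topology == "regular") k <- round(k)
  }
  if (k < 1 || k > n_genes)
    stop(sprintf("`k` must satisfy 1 <= k <= n_genes, got k = %s, n_genes = %d",
                 format(k), n_genes), call. = FALSE)
  if (topology == "regular" && k != round(k))
    stop("regular topology needs an integer `k`", call. = FALSE)
  structure(
    list(n_genes = n_genes, k = k, density = k / n_genes,
         conn_mode = conn_mode,
         topology = topology, weight_scheme = weight_scheme,
         allow_self_loops = isTRUE(allow_self_loops),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("<ensemble_spec>\n")
  cat(sprintf("  N = %d, k = %s (density %.4g)\n",
              x$n_genes, format(x$k), x$density))
  cat(sprintf("  topology = %s, weights = %s, self-loops %s\n",
              x$topology, x$weight_scheme,
              if (x$allow_self_loops) "allowed" else "forbidden"))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Write and read ensemble specifications as flat key-value files
#'
#' The on-disk form is a flat YAML mapping with the same field names as
#' [ensemble_spec()]: `n_genes`, `k`, `topology`, `weight_scheme`,
#' `allow_self_loops`, `seed`.
#'
#' @param spec an `ensemble_spec`.
#' @param path file path.
#' @return `read_ensemble_spec` returns an `ensemble_spec`;
#'   `write_ensemble_spec` returns `path` invisibly.
#' @export
write_ensemble_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ensemble_spec"))
  fields <- spec[c("n_genes", "k", "topology", "weight_scheme",
                   "allow_self_loops")]
  if (!is.null(spec$seed)) fields$seed <- spec$seed
  yaml::write_yaml(fields, path)
  invisible(path)
}

#' @rdname write_ensemble_spec
#' @export
read_ensemble_spec <- function(path) {
  fields <- yaml::read_yaml(path)
  known <- c("n_genes", "k", "density", "topology", "weight_scheme",
             "allow_self_loops", "seed")
  bad <- setdiff(names(fields), known)
  if (length(bad))
    stop("unknown ensemble fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(ensemble_spec, fields)
}

#' Export an interaction matrix
#'
#' `write_edge_list` writes the nonzero entries as a three-column TSV
#' (`source`, `target`, `weight`, with `w[target, source]` the effect of
#' `source` on `target`); `write_dense_matrix` writes the full N x N matrix
#' as TSV.
#'
#' @param w numeric interaction matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(w, path) {
  idx <- which(w != 0, arr.ind = TRUE)
  edges <- data.frame(source = idx[, "col"], target = idx[, "row"],
                      weight = w[idx])
  edges <- edges[order(edges$source, edges$target), ]
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_dense_matrix <- function(w, path) {
  write.table(w, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
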