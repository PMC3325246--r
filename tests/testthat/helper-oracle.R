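# Independent brute-force oracle for the discrete dynamics: build the full
# 2^N-node functional graph with plain matrix arithmetic, peel non-cycle
# nodes by repeated in-degree-0 removal, and read off each state's attractor
# period and transient. Deliberately shares no code with the package's
# hashing-based iterator.
oracle_census <- function(w, map = "pm1", zero_value = NULL) {
  n <- nrow(w)
  off <- if (map == "pm1") -1L else 0L
  if (is.null(zero_value)) zero_value <- off  # "minus" convention
  states <- as.matrix(expand.grid(rep(list(c(off, 1L)), n)))
  m <- nrow(states)
  keys <- apply(states, 1, paste, collapse = ",")
  idx <- stats::setNames(seq_len(m), keys)
  nxt <- integer(m)
  for (s in seq_len(m)) {
    h <- drop(w %*% states[s, ])
    y <- ifelse(h > 0, 1L, ifelse(h < 0, off, zero_value))
    nxt[s] <- idx[[paste(y, collapse = ",")]]
  }
  indeg <- tabulate(nxt, nbins = m)
  queue <- which(indeg == 0L)
  on_cycle <- rep(TRUE, m)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    on_cycle[v] <- FALSE
    t <- nxt[v]
    indeg[t] <- indeg[t] - 1L
    if (indeg[t] == 0L) queue <- c(queue, t)
  }
  cycle_len <- rep(NA_integer_, m)
  for (s in which(on_cycle)) {
    if (!is.na(cycle_len[s])) next
    cyc <- s; v <- nxt[s]
    while (v != s) { cyc <- c(cyc, v); v <- nxt[v] }
    cycle_len[cyc] <- length(cyc)
  }
  transient <- integer(m); per <- integer(m)
  for (s in seq_len(m)) {
    v <- s; t <- 0L
    while (!on_cycle[v]) { v <- nxt[v]; t <- t + 1L }
    transient[s] <- t
    per[s] <- cycle_len[v]
  }
  list(states = states, period = per, transient = transient,
       outcome = ifelse(per == 1L, "fixed_point", "cycle"))
}

# degenerate single-matrix "ensembles" for calibration tests
constant_ensemble <- function(w) function() w
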