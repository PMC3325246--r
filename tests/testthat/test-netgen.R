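test_that("ensemble specs validate their parameters", {
  expect_error(ensemble_spec(5, k = 6), "1 <= k <= n_genes")
  expect_error(ensemble_spec(5, k = 0), "1 <= k <= n_genes")
  expect_error(ensemble_spec(5), "one of")
  expect_error(ensemble_spec(5, density = 1.2), "\\(0, 1\\]")
  expect_error(ensemble_spec(4, k = 2, density = 0.9), "disagree")
  spec <- ensemble_spec(10, density = 0.2)
  expect_equal(spec$k, 2)
  expect_equal(ensemble_spec(10, k = 2)$density, 0.2)
})

test_that("regular generation gives exactly K nonzero entries per row", {
  set.seed(11)
  spec <- ensemble_spec(12, k = 3)
  for (i in 1:300) {
    w <- generate_matrix(spec)
    expect_equal(rowSums(w != 0), rep(3, 12))
    expect_true(all(w %in% c(-1, 0, 1)))
  }
  # full density forces every entry nonzero
  w <- generate_matrix(ensemble_spec(2, k = 2))
  expect_true(all(w != 0))
  # K = 1: one input per gene
  w <- generate_matrix(ensemble_spec(5, k = 1))
  expect_equal(rowSums(w != 0), rep(1, 5))
})

test_that("self-loop flag controls the diagonal", {
  set.seed(2)
  spec <- ensemble_spec(6, k = 5, allow_self_loops = FALSE)
  for (i in 1:50) expect_true(all(diag(generate_matrix(spec)) == 0))
  expect_error(generate_matrix(ensemble_spec(4, k = 4,
                                             allow_self_loops = FALSE)),
               "self-loops")
})

test_that("gaussian weights are real and nonzero where present", {
  set.seed(3)
  w <- generate_matrix(ensemble_spec(8, k = 4,
                                     weight_scheme = "real_gaussian"))
  nz <- w[w != 0]
  expect_equal(length(nz), 32)
  expect_false(any(nz %in% c(-1, 1)))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- ensemble_spec(10, k = 4, seed = 99)
  expect_identical(generate_ensemble(spec, 5), generate_ensemble(spec, 5))
  for (topo in c("poisson", "bio_exp_in_pow_out")) {
    spec <- ensemble_spec(20, k = 2, topology = topo, seed = 42)
    expect_identical(generate_ensemble(spec, 3), generate_ensemble(spec, 3))
  }
})

test_that("poisson in-degrees have mean K and allow empty rows", {
  set.seed(4)
  spec <- ensemble_spec(500, k = 2, topology = "poisson")
  degs <- unlist(lapply(1:20, function(i) rowSums(generate_matrix(spec) != 0)))
  # 10^4 sampled genes; truncation at N = 500 is negligible for mean 2
  se <- sqrt(2 / length(degs))
  expect_lt(abs(mean(degs) - 2), 3 * se)
  expect_gt(sum(degs == 0), 0)  # in-degree-0 rows are legal all-zero rows
  expect_true(all(degs <= 500))
})

test_that("biological topology has mean-K in-degrees and heavy-tailed out-degrees", {
  set.seed(5)
  spec <- ensemble_spec(500, k = 2, topology = "bio_exp_in_pow_out")
  mats <- lapply(1:20, function(i) generate_matrix(spec))
  indeg <- unlist(lapply(mats, function(w) rowSums(w != 0)))
  # discretized exponential with mean 2: sd is close to sqrt(mean*(mean+1))
  se <- stats::sd(indeg) / sqrt(length(indeg))
  expect_lt(abs(mean(indeg) - 2), 3 * se)
  outdeg <- unlist(lapply(mats, function(w) colSums(w != 0)))
  # heavy tail: far more mass beyond 10x the mean than the exponential
  # (geometric) law with the same mean would allow
  p_tail <- mean(outdeg > 20)
  p_geom <- stats::pgeom(20, 1 / (1 + 2), lower.tail = FALSE)
  expect_gt(p_tail, 3 * p_geom)
  # smallest case stays well-formed
  w <- generate_matrix(ensemble_spec(2, k = 1, topology = "bio_exp_in_pow_out"))
  expect_equal(dim(w), c(2L, 2L))
  # mean in-degree above the truncated-exponential ceiling is refused
  expect_error(generate_matrix(ensemble_spec(4, k = 2.2,
                                             topology = "bio_exp_in_pow_out")),
               "not attainable")
})

test_that("mean density matches c across topologies", {
  set.seed(6)
  for (topo in c("regular", "poisson", "bio_exp_in_pow_out")) {
    spec <- ensemble_spec(100, k = 2, topology = topo)
    dens <- vapply(1:50, function(i) mean(generate_matrix(spec) != 0),
                   numeric(1))
    expect_lt(abs(mean(dens) - 0.02),
              3 * stats::sd(dens) / sqrt(length(dens)) + 1e-12)
  }
})

test_that("state enumeration is exhaustive and maps are respected", {
  s3 <- enumerate_states(3, "pm1")
  expect_equal(nrow(s3), 8)
  expect_equal(nrow(unique(s3)), 8)
  expect_true(all(s3 %in% c(-1L, 1L)))
  s1 <- enumerate_states(1, "zero_one")
  expect_setequal(as.vector(s1), c(0L, 1L))
  expect_error(enumerate_states(30, "pm1"), "guard")
})

test_that("random initial states are uniform over the state space", {
  set.seed(7)
  draws <- replicate(1e5, paste(random_initial_state(4, "pm1"),
                                collapse = ""))
  counts <- table(draws)
  expect_equal(length(counts), 16L)
  # binomial sampling: each state within 5 SD of 1e5/16
  sd_count <- sqrt(1e5 * (1 / 16) * (15 / 16))
  expect_true(all(abs(counts - 1e5 / 16) < 5 * sd_count))
})

test_that("binary matrix enumeration is exhaustive and duplicate-free", {
  cases <- list(c(2, 2, 16), c(1, 1, 2), c(2, 1, 16), c(3, 3, 512))
  for (cs in cases) {
    en <- enumerate_binary_matrices(cs[1], cs[2])
    expect_equal(en$count, cs[3])
    seen <- character(0)
    while (!is.null(w <- en$nxt())) {
      expect_equal(rowSums(w != 0), rep(cs[2], cs[1]), ignore_attr = TRUE)
      seen <- c(seen, paste(w, collapse = ","))
    }
    expect_equal(length(seen), cs[3])
    expect_equal(length(unique(seen)), cs[3])
  }
  expect_error(enumerate_binary_matrices(6, 6), "guard")
  en <- enumerate_binary_matrices(1, 1)
  en$nxt(); en$reset()
  expect_equal(en$nxt(), matrix(-1, 1, 1))
})

test_that("ensemble specs round-trip through their key-value file form", {
  spec <- ensemble_spec(17, k = 3, topology = "poisson",
                        weight_scheme = "real_gaussian",
                        allow_self_loops = FALSE, seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ensemble_spec(spec, path)
  back <- read_ensemble_spec(path)
  expect_equal(back[names(back) != "seed"], spec[names(spec) != "seed"])
  expect_equal(back$seed, 5L)
})

test_that("matrices export as edge lists and dense text", {
  w <- matrix(c(0, 1.5, -1, 0), 2, 2, byrow = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(w, path)
  edges <- read.delim(path)
  expect_equal(nrow(edges), 2)
  # w[target, source]: gene 1 is activated by gene 2, gene 2 repressed by 1
  expect_equal(edges$weight[edges$source == 2 & edges$target == 1], 1.5)
  expect_equal(edges$weight[edges$source == 1 & edges$target == 2], -1)
  write_dense_matrix(w, path)
  expect_equal(as.matrix(read.delim(path, header = FALSE)), w,
               ignore_attr = TRUE)
})
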