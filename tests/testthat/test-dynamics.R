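test_that("a stored pattern generates a self-consistent field", {
  set.seed(1)
  top <- build_small_world(500, 20, 0.1)
  pat <- make_patterns(500, 1, 0)
  net <- embed_native(top, pat)
  st <- network_state(pat, 0.5, init = "native")
  f <- local_fields(net, st)
  # each incoming term is xi_i xi_j xi_j = xi_i, so h = xi exactly
  expect_equal(f$total, pat$native[, 1])
  expect_equal(f$external_part, rep(0, 500))
})

test_that("local fields match the hand-computed 3-node example", {
  fx <- three_node_fixture()
  st <- network_state(fx$pat, 1)
  st$s <- c(1, 1, 1)
  f <- local_fields(fx$net, st)
  # h_i = (row sums of J) / k with k = 2
  expect_equal(f$total, c((0 - 1) / 2, 0, (-1 + 0) / 2))
})

test_that("field decompositions are bookkeeping: parts sum to the total", {
  fx <- small_wired(seed = 2)
  st <- network_state(fx$pat, 1, init = "random", seed = 3)
  f <- local_fields(fx$net, st, "fixed_neurons")
  expect_equal(f$native_part + f$external_part, f$total)
  # global field with w_ext = 0 adds nothing
  g <- local_fields(fx$net, st, "global", w_ext = 0, xi_new = fx$pat$new)
  expect_equal(g$external_part, rep(0, fx$net$n_neurons))
  expect_equal(g$total, g$native_part)
  # global field adds (w_ext/p) xi^e to every neuron
  g2 <- local_fields(fx$net, st, "global", w_ext = 2, xi_new = fx$pat$new)
  expect_equal(g2$total - g$total, 2 * fx$pat$new)
})

test_that("alignment frequency follows the heat-bath probability", {
  pat <- make_patterns(1e5, 1, 0, seed = 4)
  # beta = 1, |h| = 0.5: alignment probability 1/(1 + e^-1) ~ 0.7311
  st <- network_state(pat, 1, init = "random", seed = 5)
  h <- rep(0.5, 1e5)
  set.seed(6)
  new <- step_state(st, structure(list(total = h), class = "cm_fields"))
  expect_equal(mean(new$s == 1), 1 / (1 + exp(-1)), tolerance = 0.01)
  # infinite-temperature limit: alignment probability exactly 1/2
  st_hot <- network_state(pat, 1e12, init = "random", seed = 7)
  set.seed(8)
  new_hot <- step_state(st_hot, structure(list(total = h), class = "cm_fields"))
  expect_equal(mean(new_hot$s == 1), 0.5, tolerance = 0.01)
  # large beta: effectively deterministic alignment
  st_cold <- network_state(pat, 1 / 50, init = "random", seed = 9)
  set.seed(10)
  new_cold <- step_state(st_cold, structure(list(total = rep(1, 1e5)),
                                            class = "cm_fields"))
  expect_true(all(new_cold$s == 1))
})

test_that("zero field carries no information: flip probability 1/2", {
  pat <- make_patterns(2e4, 1, 0, seed = 11)
  st <- network_state(pat, 1, init = "random", seed = 12)
  set.seed(13)
  new <- step_state(st, structure(list(total = rep(0, 2e4)),
                                  class = "cm_fields"))
  expect_equal(mean(new$s != st$s), 0.5, tolerance = 0.02)
})

test_that("overlap is an absolute mean agreement with exclusions", {
  xi <- c(1, -1, 1, 1, -1)
  expect_equal(overlap(xi, xi), 1)
  expect_equal(overlap(-xi, xi), 1)  # sign symmetry
  expect_equal(overlap(c(1, 1, 1, 1, -1), xi, excluded = 2L), 1)
  expect_error(overlap(xi, xi, excluded = 1:5), "every neuron")
  # random states: overlap ~ 0 with sd ~ 1/sqrt(N)
  set.seed(14)
  n <- 10000
  ov <- replicate(100, overlap(sample(c(-1, 1), n, TRUE),
                               sample(c(-1, 1), n, TRUE)))
  expect_lt(mean(ov), 3 / sqrt(n))
  expect_equal(stats::sd(ov), sqrt(1 - 2 / pi) / sqrt(n), tolerance = 0.5)
})

test_that("the native attractor is stable deep in the sub-critical regime", {
  set.seed(15)
  top <- build_small_world(500, 20, 0.1)
  pat <- make_patterns(500, 1, 0)
  net <- embed_native(top, pat)
  for (T in c(0.01, 0.2)) {
    st <- network_state(pat, T, init = "native")
    tr <- evolve(net, pat, st, 200)
    expect_true(all(tr$overlap_native[, 1] > 0.95))
  }
  # at T = 0.01 the expected number of state changes is zero
  st <- network_state(pat, 0.01, init = "native")
  tr <- evolve(net, pat, st, 100)
  expect_equal(sum(tr$flip_fraction), 0)
})

test_that("the super-critical network flips about half its neurons per sweep", {
  set.seed(16)
  top <- build_small_world(1000, 20, 0.1)
  pat <- make_patterns(1000, 1, 0)
  net <- embed_native(top, pat)
  st <- network_state(pat, 100, init = "random")
  tr <- evolve(net, pat, st, 100)
  expect_true(mean(tr$flip_fraction) > 0.48 && mean(tr$flip_fraction) < 0.52)
  expect_lt(mean(tail(tr$overlap_native[, 1], 50)), 0.1)
})

test_that("clamped input neurons never change state", {
  fx <- small_wired(seed = 17)
  st <- network_state(fx$pat, 1.5, init = "random", seed = 18)
  tr <- evolve(fx$net, fx$pat, st, 50, field_mode = "fixed_neurons")
  expect_equal(tr$state$s[fx$pat$input_set],
               fx$pat$new[fx$pat$input_set])
  # single iteration returns series of length 1
  tr1 <- evolve(fx$net, fx$pat, st, 1, field_mode = "fixed_neurons")
  expect_length(tr1$overlap_new, 1L)
})

test_that("asynchronous schedule preserves clamping and the ordered regime", {
  fx <- small_wired(n = 100, k = 10, input_size = 7, seed = 19)
  st <- network_state(fx$pat, 0.05, init = "native")
  set.seed(20)
  tr <- evolve(fx$net, fx$pat, st, 10, field_mode = "fixed_neurons",
               schedule = "asynchronous")
  expect_equal(tr$state$s[fx$pat$input_set], fx$pat$new[fx$pat$input_set])
  expect_gt(mean(tr$overlap_native[, 1]), 0.8)
})

test_that("trajectories export as tidy CSV with metadata", {
  fx <- small_wired(n = 80, k = 8, input_size = 0, seed = 21)
  st <- network_state(fx$pat, 1, init = "random", seed = 22)
  tr <- evolve(fx$net, fx$pat, st, 5)
  f <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, f, metadata = list(seed = 22, temperature = 1))
  df <- read.csv(f)
  expect_equal(nrow(df), 5L)
  expect_equal(df$overlap_native, as.vector(tr$overlap_native))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$seed, 22L)
  unlink(c(f, paste0(f, ".json")))
})
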