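test_that("the Hebbian step matches hand-applied weight changes", {
  fx <- three_node_fixture()
  st <- network_state(fx$pat, 1)
  st$s <- c(1, -1, 1)
  net <- hebbian_step(fx$net, st, 0.1)
  # Delta J_ij = eps * S_i * S_j
  expect_equal(J_entry(net, 1, 2), 0 - 0.1)
  expect_equal(J_entry(net, 1, 3), -1 + 0.1)
  expect_equal(J_entry(net, 2, 3), 0 - 0.1)
  # eps = 0 is a no-op
  expect_equal(hebbian_step(fx$net, st, 0)$J@x, fx$net$J@x)
  expect_error(hebbian_step(fx$net, st, -0.1), "eps")
})

test_that("a uniform state increases every eligible weight by exactly eps", {
  fx <- small_wired(n = 100, k = 10, input_size = 0, seed = 23)
  st <- network_state(fx$pat, 1)
  st$s <- rep(1, 100)
  net <- hebbian_step(fx$net, st, 0.1)
  expect_equal(net$J@x - fx$net$J@x, rep(0.1, length(fx$net$J@x)))
})

test_that("plasticity spares edges targeting clamped neurons", {
  fx <- small_wired(n = 100, k = 10, input_size = 8, seed = 24)
  st <- network_state(fx$pat, 1, init = "random", seed = 25)
  net <- hebbian_step(fx$net, st, 0.1)
  to_fixed <- fx$net$edge_tgt %in% fx$pat$input_set
  expect_equal(net$J@x[to_fixed], fx$net$J@x[to_fixed])
  # edges sourced at clamped neurons ARE updated by default ...
  from_fixed <- fx$net$edge_src %in% fx$pat$input_set & !to_fixed
  expect_true(all(net$J@x[from_fixed] != fx$net$J@x[from_fixed]))
  # ... and frozen under the sensitivity flag
  net2 <- hebbian_step(fx$net, st, 0.1, update_input_edges = FALSE)
  expect_equal(net2$J@x[from_fixed], fx$net$J@x[from_fixed])
})

test_that("plasticity-off evolution never changes any weight", {
  fx <- small_wired(seed = 26)
  st <- network_state(fx$pat, 1.2, init = "random", seed = 27)
  tr <- evolve(fx$net, fx$pat, st, 30, field_mode = "fixed_neurons")
  expect_identical(tr$network$J@x, fx$net$J@x)
})

test_that("learning sweeps with eps = 0 leave the pre-learning curves unchanged", {
  sw <- protocol_learn_sweep(c(0.5, 1.0, 1.5), 200, 40, p = 1,
                             input_size = 14, input_weight = 3, eps = 0,
                             phases = c(pre = 40, learn = 40, post = 40),
                             realizations = 3, seed = 28)
  sm <- summarize_sweep(sw)
  # without plasticity post-learning equals pre-learning within sampling error
  expect_true(all(abs(sm$m_new_post - sm$m_new_pre) < 0.1))
  expect_true(all(abs(sm$m_native_post - sm$m_native_pre) < 0.15))
})

test_that("clamping the native pattern extends its stability to higher T", {
  temps <- seq(0.6, 1.6, 0.2)
  plain <- summarize_sweep(protocol_prelearn_sweep(
    temps, 300, 60, p = 1, input_size = 0, realizations = 5, seed = 29))
  recall <- summarize_sweep(protocol_prelearn_sweep(
    temps, 300, 60, p = 1, input_size = 21, input_weight = 3,
    realizations = 5, recall_native = TRUE, seed = 29))
  tc_plain <- tc_from_halfmax(plain$temperature, plain$m_native)$t_c
  tc_recall <- tc_from_halfmax(recall$temperature, recall$m_native)$t_c
  expect_gt(tc_recall, tc_plain)
})

test_that("agreement with the new configuration grows with input connectivity", {
  set.seed(30)
  top <- build_small_world(400, 80, 0.1)
  pat <- make_patterns(400, 1, 28)
  net <- wire_input(embed_native(top, pat), pat, 3)
  st <- network_state(pat, 1.0, init = "random")
  tr <- evolve(net, pat, st, 80, field_mode = "fixed_neurons")
  tab <- input_degree_overlap(net, pat, tr$state)
  expect_equal(sum(tab$n_neurons), 400 - 28)  # clamped neurons excluded
  # agreement in the most-connected half exceeds the least-connected half
  half <- tab$n_input_connections > stats::median(tab$n_input_connections)
  expect_gt(stats::weighted.mean(tab$agreement[half], tab$n_neurons[half]),
            stats::weighted.mean(tab$agreement[!half], tab$n_neurons[!half]))
})

test_that("peak consolidation is monotone in input strength", {
  grid <- protocol_input_robustness(
    input_sizes = 28, input_weights = c(1, 3), temperatures = c(0.8, 1.0, 1.2),
    n_neurons = 400, in_degree = 80, p = 1, eps = 0.1,
    phases = c(pre = 50, learn = 200, post = 50), realizations = 3, seed = 31)
  g <- grid[order(grid$input_weight), ]
  expect_true(all(diff(g$peak_delta_m_new) >= -0.05))
  expect_gt(g$peak_delta_m_new[2], g$peak_delta_m_new[1])
  # no input, no consolidation
  zero <- protocol_input_robustness(
    input_sizes = 0, input_weights = 3, temperatures = c(1.0),
    n_neurons = 400, in_degree = 80, realizations = 1, seed = 31)
  expect_equal(zero$peak_delta_m_new, 0)
})

test_that("a global persistent field consolidates only when strong and near T_c", {
  res <- protocol_global_field(
    w_ext_values = c(0, 1), temperatures = c(0.5, 1.0, 2.0),
    n_neurons = 400, in_degree = 80, p = 1, eps = 0.1,
    phases = c(pre = 50, learn = 150, post = 50), realizations = 3, seed = 32)
  # w_ext = 0 reduces to the no-input system: native stable below T_c,
  # nothing stable above
  w0 <- res[res$w_ext == 0, ]
  expect_equal(w0$class[w0$temperature == 0.5], "native")
  expect_equal(w0$class[w0$temperature == 2.0], "neither")
  # a strong field near T_c makes the new configuration stable
  w1 <- res[res$w_ext == 1, ]
  expect_equal(w1$class[w1$temperature == 1.0], "new")
})

test_that("consolidation time is short near T_c and censored deep sub-critically", {
  set.seed(33)
  top <- build_small_world(400, 80, 0.1)
  pat <- make_patterns(400, 1, 28)
  net <- wire_input(embed_native(top, pat), pat, 3)
  near <- consolidation_time(net, pat, 1.3, 0.1, 300, seed = 34)
  expect_false(near$censored)
  expect_lt(near$time, 150)
  cold <- consolidation_time(net, pat, 0.1, 0.1, 300, seed = 35)
  expect_true(cold$censored)
  expect_true(is.na(cold$time))
})
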