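# hand-checkable 3-node fixture: full digraph (k = 2), two stored patterns
# xi1 = (+, +, -), xi2 = (+, -, -); outer-product couplings worked out by hand:
#   J12 = (1*1 + 1*(-1))/2 = 0     J13 = (1*(-1) + 1*(-1))/2 = -1
#   J21 = 0   J23 = ((1)(-1) + (-1)(-1))/2 = 0
#   J31 = -1  J32 = 0
three_node_fixture <- function() {
  top <- build_small_world(3, 2, 0)
  pat <- make_patterns(3, 2, 0, seed = 1)
  pat$native <- cbind(c(1, 1, -1), c(1, -1, -1))
  list(top = top, pat = pat, net = embed_native(top, pat))
}

# dense weight lookup for small networks
J_entry <- function(net, i, j) as.numeric(net$J[i, j])

# small wired network for protocol-level tests
small_wired <- function(n = 200, k = 40, p = 1, input_size = 14,
                        input_weight = 3, seed = 1) {
  set.seed(seed)
  top <- build_small_world(n, k, 0.1)
  pat <- make_patterns(n, p, input_size)
  net <- embed_native(top, pat)
  if (input_size > 0) net <- wire_input(net, pat, input_weight)
  list(top = top, pat = pat, net = net)
}
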