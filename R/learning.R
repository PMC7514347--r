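#' One Hebbian state-based plasticity step
#'
#' Applies the unbounded state-based rule `J_ij <- J_ij + eps * S_i * S_j` to
#' every edge `j -> i` whose target `i` is not a clamped input neuron.
#' Clamped neurons receive no relevant input (their states never change), so
#' edges *targeting* them are left untouched; edges *sourced* at them are
#' plastic -- their output shapes the rest of the network. No weight bound or
#' decay is applied.
#'
#' @param network a `cm_network`.
#' @param state a `cm_state`.
#' @param eps learning rate (>= 0; 0 is a no-op).
#' @param update_input_edges if `FALSE`, edges sourced at clamped input
#'   neurons are also frozen (sensitivity flag; default `TRUE`).
#' @return the updated network.
#' @export
hebbian_step <- function(network, state, eps, update_input_edges = TRUE) {
  if (eps < 0) stop("eps must be >= 0")
  if (eps == 0) return(network)
  mask <- network$plastic
  if (!update_input_edges && length(network$input_set) > 0L) {
    in_input <- logical(network$n_neurons)
    in_input[network$input_set] <- TRUE
    mask <- mask & !in_input[network$edge_src]
  }
  s <- state$s
  network$J@x[mask] <- network$J@x[mask] +
    eps * s[network$edge_tgt[mask]] * s[network$edge_src[mask]]
  network
}

# build one realization: topology + patterns + couplings (+ wired input)
build_realization <- function(n_neurons, in_degree, p, input_size,
                              input_weight, rewire_prob, recall_native = FALSE) {
  top <- build_small_world(n_neurons, in_degree, rewire_prob)
  pat <- make_patterns(n_neurons, p, input_size)
  if (recall_native) pat$new <- pat$native[, 1]
  net <- embed_native(top, pat)
  if (input_size > 0L) net <- wire_input(net, pat, input_weight)
  list(net = net, pat = pat)
}

# tail means of a trajectory: final-state order parameters averaged over the
# last `avg_last` iterations to suppress single-step noise
traj_tail <- function(traj, avg_last) {
  n_it <- length(traj$overlap_new)
  idx <- max(1L, n_it - avg_last + 1L):n_it
  list(m_native = max(colMeans(traj$overlap_native[idx, , drop = FALSE])),
       m_new = mean(traj$overlap_new[idx]),
       flip = mean(traj$flip_fraction[idx]))
}

#' Pre-learning temperature sweep
#'
#' For every temperature and realization: build a network, wire the external
#' input for the new configuration (or, with `recall_native = TRUE`, clamp
#' the input neurons to the first native memory, the memory-recall variant),
#' relax from a random state without plasticity, and record the final
#' overlaps with the native memories (max over memories) and the new
#' configuration, plus the flip fraction.
#'
#' @param temperatures ascending temperature grid.
#' @param n_neurons,in_degree,p,input_size,input_weight,rewire_prob network
#'   parameters.
#' @param realizations number of independent network realizations.
#' @param n_iter relaxation iterations per temperature.
#' @param avg_last number of final iterations averaged into the reported
#'   order parameters.
#' @param recall_native clamp input neurons to the native memory instead of a
#'   new configuration?
#' @param seed integer seed; realization `r` uses `seed + r`.
#' @return a data.frame of class `cm_sweep` with one row per (temperature,
#'   realization): `temperature`, `realization`, `m_native`, `m_new`, `flip`.
#' @export
protocol_prelearn_sweep <- function(temperatures, n_neurons, in_degree,
                                    p = 1, input_size = 0, input_weight = 3,
                                    rewire_prob = 0.1, realizations = 10,
                                    n_iter = 100, avg_last = 10,
                                    recall_native = FALSE, seed = 1) {
  stopifnot(all(diff(temperatures) > 0), realizations >= 1)
  mode <- if (input_size > 0) "fixed_neurons" else "none"
  out <- vector("list", realizations)
  for (r in seq_len(realizations)) {
    set.seed(seed + r)
    rl <- build_realization(n_neurons, in_degree, p, input_size,
                            input_weight, rewire_prob, recall_native)
    rows <- lapply(temperatures, function(T) {
      st <- network_state(rl$pat, T, init = "random")
      traj <- evolve(rl$net, rl$pat, st, n_iter, field_mode = mode)
      tl <- traj_tail(traj, avg_last)
      data.frame(temperature = T, realization = r,
                 m_native = tl$m_native, m_new = tl$m_new, flip = tl$flip)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  attr(res, "params") <- list(n_neurons = n_neurons, in_degree = in_degree,
                              p = p, input_size = input_size,
                              input_weight = input_weight, seed = seed,
                              n_iter = n_iter, recall_native = recall_native)
  class(res) <- c("cm_sweep", "data.frame")
  res
}

#' Learning temperature sweep (pre / learning / post phases)
#'
#' Per temperature and realization: relax without plasticity (pre phase),
#' then interleave one synchronous dynamics step with one Hebbian step for
#' `phases["learn"]` iterations, then relax again with plasticity off (post
#' phase; the input stays wired / the field stays on unless noted). Records
#' the tail-averaged order parameters and flip fractions of the pre and post
#' phases. Couplings are reset between temperatures: learning at one
#' temperature never leaks into another.
#'
#' @inheritParams protocol_prelearn_sweep
#' @param eps Hebbian learning rate (> 0).
#' @param phases named integer vector `c(pre =, learn =, post =)`.
#' @return a data.frame of class `cm_sweep` with pre/post columns
#'   (`m_native_pre`, `m_new_pre`, `flip_pre`, `m_native_post`,
#'   `m_new_post`, `flip_post`).
#' @export
protocol_learn_sweep <- function(temperatures, n_neurons, in_degree,
                                 p = 1, input_size, input_weight, eps = 0.1,
                                 phases = c(pre = 100, learn = 500, post = 100),
                                 rewire_prob = 0.1, realizations = 10,
                                 avg_last = 10, seed = 1) {
  stopifnot(all(diff(temperatures) > 0), eps >= 0,
            all(c("pre", "learn", "post") %in% names(phases)))
  mode <- if (input_size > 0) "fixed_neurons" else "none"
  out <- vector("list", realizations)
  for (r in seq_len(realizations)) {
    set.seed(seed + r)
    rl <- build_realization(n_neurons, in_degree, p, input_size,
                            input_weight, rewire_prob)
    rows <- lapply(temperatures, function(T) {
      st <- network_state(rl$pat, T, init = "random")
      pre <- evolve(rl$net, rl$pat, st, phases[["pre"]], field_mode = mode)
      tl_pre <- traj_tail(pre, avg_last)
      lrn <- evolve(rl$net, rl$pat, pre$state, phases[["learn"]],
                    field_mode = mode, eps = eps)
      post <- evolve(lrn$network, rl$pat, lrn$state, phases[["post"]],
                     field_mode = mode)
      tl_post <- traj_tail(post, avg_last)
      data.frame(temperature = T, realization = r,
                 m_native_pre = tl_pre$m_native, m_new_pre = tl_pre$m_new,
                 flip_pre = tl_pre$flip,
                 m_native_post = tl_post$m_native, m_new_post = tl_post$m_new,
                 flip_post = tl_post$flip)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  attr(res, "params") <- list(n_neurons = n_neurons, in_degree = in_degree,
                              p = p, input_size = input_size,
                              input_weight = input_weight, eps = eps,
                              phases = phases, seed = seed)
  class(res) <- c("cm_sweep", "data.frame")
  res
}

#' Summarize a sweep: mean and standard error per temperature
#'
#' @param sweep a `cm_sweep` data.frame.
#' @return a data.frame with one row per temperature; for every measured
#'   column `x` the mean `x` and its standard error `x_sem` across
#'   realizations.
#' @export
summarize_sweep <- function(sweep) {
  vars <- setdiff(names(sweep), c("temperature", "realization"))
  temps <- sort(unique(sweep$temperature))
  rows <- lapply(temps, function(T) {
    sub <- sweep[sweep$temperature == T, , drop = FALSE]
    means <- vapply(vars, function(v) mean(sub[[v]]), numeric(1))
    sems <- vapply(vars, function(v)
      stats::sd(sub[[v]]) / sqrt(nrow(sub)), numeric(1))
    names(sems) <- paste0(vars, "_sem")
    as.data.frame(c(list(temperature = T), as.list(means), as.list(sems)))
  })
  out <- do.call(rbind, rows)
  out$realizations <- length(unique(sweep$realization))
  out
}

#' New-configuration agreement grouped by input connectivity
#'
#' Groups the non-clamped neurons by how many of their incoming edges
#' originate in the input subset `N'`, and reports the mean per-neuron
#' agreement `xi^e_i * S_i` per group. At criticality the agreement grows
#' with the number of input connections and exceeds the sub- and
#' super-critical regimes.
#'
#' @param network a wired `cm_network`.
#' @param patterns the pattern set.
#' @param state the final `cm_state`.
#' @return a data.frame: `n_input_connections`, `agreement`, `n_neurons`.
#' @export
input_degree_overlap <- function(network, patterns, state) {
  if (length(network$input_set) == 0L) stop("input is not wired")
  in_input <- logical(network$n_neurons)
  in_input[network$input_set] <- TRUE
  sel <- in_input[network$edge_src]
  cnt <- tabulate(network$edge_tgt[sel], nbins = network$n_neurons)
  free <- which(!in_input)
  agree <- patterns$new[free] * state$s[free]
  grp <- cnt[free]
  agg <- stats::aggregate(agree, by = list(n_input_connections = grp), FUN = mean)
  n_per <- as.vector(table(factor(grp, levels = agg$n_input_connections)))
  data.frame(n_input_connections = agg$n_input_connections,
             agreement = agg$x, n_neurons = n_per)
}

#' Robustness of consolidation to input size and strength
#'
#' For each (input size, input weight) pair runs a full learning temperature
#' sweep and reports the peak (over temperature) change in the
#' new-configuration overlap from pre- to post-learning.
#'
#' @param input_sizes vector of input subset sizes (neuron counts).
#' @param input_weights vector of `w_e` values.
#' @inheritParams protocol_learn_sweep
#' @return a data.frame: `input_size`, `input_weight`, `peak_delta_m_new`.
#' @export
protocol_input_robustness <- function(input_sizes, input_weights,
                                      temperatures, n_neurons, in_degree,
                                      p = 1, eps = 0.1,
                                      phases = c(pre = 100, learn = 500, post = 100),
                                      rewire_prob = 0.1, realizations = 5,
                                      seed = 1) {
  grid <- expand.grid(input_size = input_sizes, input_weight = input_weights)
  grid$peak_delta_m_new <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sz <- grid$input_size[g]
    if (sz == 0) { grid$peak_delta_m_new[g] <- 0; next }
    sw <- protocol_learn_sweep(temperatures, n_neurons, in_degree, p,
                               input_size = sz,
                               input_weight = grid$input_weight[g],
                               eps = eps, phases = phases,
                               rewire_prob = rewire_prob,
                               realizations = realizations, seed = seed)
    sm <- summarize_sweep(sw)
    grid$peak_delta_m_new[g] <- max(sm$m_new_post - sm$m_new_pre)
  }
  grid
}

#' Global persistent-field learning map
#'
#' For each (field strength, temperature): pre-learning relaxation with the
#' global field on, a learning phase with the field on, then a field-off
#' relaxation. Classifies the outcome by the final overlaps: `"native"`
#' (m_native >= threshold > m_new), `"new"` (m_new >= threshold > m_native),
#' or `"neither"`.
#'
#' @param w_ext_values vector of global field strengths.
#' @inheritParams protocol_learn_sweep
#' @param threshold stability classification threshold (default 0.45).
#' @return a data.frame: `w_ext`, `temperature`, `m_native`, `m_new`,
#'   `delta` (m_new - m_native), `class`.
#' @export
protocol_global_field <- function(w_ext_values, temperatures, n_neurons,
                                  in_degree, p = 1, eps = 0.1,
                                  phases = c(pre = 100, learn = 500, post = 100),
                                  rewire_prob = 0.1, realizations = 5,
                                  avg_last = 10, threshold = 0.45, seed = 1) {
  stopifnot(eps > 0)
  out <- list()
  for (w in w_ext_values) {
    acc <- array(0, c(length(temperatures), 2))
    for (r in seq_len(realizations)) {
      set.seed(seed + r)
      rl <- build_realization(n_neurons, in_degree, p, input_size = 0,
                              input_weight = 1, rewire_prob = rewire_prob)
      for (ti in seq_along(temperatures)) {
        st <- network_state(rl$pat, temperatures[ti], init = "random")
        pre <- evolve(rl$net, rl$pat, st, phases[["pre"]],
                      field_mode = "global", w_ext = w)
        lrn <- evolve(rl$net, rl$pat, pre$state, phases[["learn"]],
                      field_mode = "global", w_ext = w, eps = eps)
        off <- evolve(lrn$network, rl$pat, lrn$state, phases[["post"]],
                      field_mode = "none")
        tl <- traj_tail(off, avg_last)
        acc[ti, ] <- acc[ti, ] + c(tl$m_native, tl$m_new)
      }
    }
    acc <- acc / realizations
    cls <- ifelse(acc[, 1] >= threshold & acc[, 2] < threshold, "native",
           ifelse(acc[, 2] >= threshold & acc[, 1] < threshold, "new",
                  "neither"))
    out[[length(out) + 1L]] <-
      data.frame(w_ext = w, temperature = temperatures,
                 m_native = acc[, 1], m_new = acc[, 2],
                 delta = acc[, 2] - acc[, 1], class = cls)
  }
  do.call(rbind, out)
}

#' Time to consolidate the new configuration
#'
#' After a plasticity-off pre-relaxation (so that learning starts from the
#' thermal state of the pre-learning system, not from the transient of a
#' random initial condition), runs the learning dynamics (input wired,
#' plasticity on) and returns the first learning iteration at which the
#' new-configuration overlap reaches the consolidation threshold
#' `m_e >= 1/2`, or flags the run as censored if the threshold is never
#' reached within `max_iterations`.
#'
#' @param network a wired `cm_network`.
#' @param patterns the pattern set.
#' @param temperature dynamical temperature.
#' @param eps learning rate.
#' @param max_iterations learning-phase simulation budget.
#' @param pre_iterations plasticity-off relaxation length before the
#'   learning clock starts (default 100).
#' @param threshold consolidation threshold on `m_e` (default 0.5).
#' @param seed optional seed.
#' @return list with `time` (integer iteration, or `NA` if censored) and
#'   `censored` (logical).
#' @export
consolidation_time <- function(network, patterns, temperature, eps,
                               max_iterations, pre_iterations = 100,
                               threshold = 0.5, seed = NULL) {
  stopifnot(max_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  mode <- if (length(network$input_set) > 0L) "fixed_neurons" else "none"
  st <- network_state(patterns, temperature, init = "random")
  excl <- patterns$input_set
  if (pre_iterations > 0) {
    pre <- evolve(network, patterns, st, pre_iterations, field_mode = mode)
    st <- pre$state
  }
  for (t in seq_len(max_iterations)) {
    f <- local_fields(network, st, mode, xi_new = patterns$new)
    st <- step_state(st, f)
    network <- hebbian_step(network, st, eps)
    if (overlap(st, patterns$new, excl) >= threshold)
      return(list(time = t, censored = FALSE))
  }
  list(time = NA_integer_, censored = TRUE)
}
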