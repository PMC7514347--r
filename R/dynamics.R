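#' Instantaneous network state
#'
#' A vector of binary neuron states (`+1` firing, `-1` quiescent) together
#' with the inverse temperature and the clamp mask for the external-input
#' neurons. When the pattern set carries a non-empty input subset and
#' `fix_input = TRUE`, the states of those neurons are set to the new
#' configuration `xi^e` and never change during evolution.
#'
#' @param patterns a [make_patterns()] object.
#' @param temperature dynamical temperature `T > 0` (`beta = 1/T`).
#' @param init `"random"` (each state +/-1 with probability 1/2), `"native"`
#'   (copy of native memory `mu`), or `"new"` (copy of `xi^e`).
#' @param mu which native memory to copy when `init = "native"`.
#' @param fix_input clamp the input neurons to `xi^e`?
#' @param seed optional seed for the random initial state.
#' @return an object of class `cm_state`: list with `s` (+/-1 vector),
#'   `fixed` (logical mask), `temperature`, `beta`.
#' @export
network_state <- function(patterns, temperature,
                          init = c("random", "native", "new"),
                          mu = 1L, fix_input = TRUE, seed = NULL) {
  stopifnot(inherits(patterns, "cm_patterns"))
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  n <- patterns$n_neurons
  s <- switch(init,
              random = sample(c(-1, 1), n, replace = TRUE),
              native = patterns$native[, mu],
              new = patterns$new)
  fixed <- logical(n)
  if (fix_input && length(patterns$input_set) > 0L) {
    fixed[patterns$input_set] <- TRUE
    s[patterns$input_set] <- patterns$new[patterns$input_set]
  }
  structure(list(s = s, fixed = fixed, temperature = temperature,
                 beta = 1 / temperature),
            class = "cm_state")
}

#' @export
print.cm_state <- function(x, ...) {
  cat(sprintf("Network state: N = %d (%d clamped), T = %g\n",
              length(x$s), sum(x$fixed), x$temperature))
  invisible(x)
}

#' Local fields acting on every neuron
#'
#' The recurrent field is `h_i = (1/k) * sum_{j -> i} J_ij S_j` over incoming
#' edges. With `field_mode = "fixed_neurons"` the clamped input sources enter
#' the sum through their rewired couplings and the returned decomposition
#' separates their contribution (bookkeeping only; the total is unchanged).
#' With `field_mode = "global"` a persistent external field
#' `(w_ext / p) * xi^e_i` is added to *every* neuron.
#'
#' @param network a `cm_network`.
#' @param state a `cm_state` of matching length.
#' @param field_mode one of `"none"`, `"fixed_neurons"`, `"global"`.
#' @param w_ext global field strength (used by `"global"` only).
#' @param xi_new the new configuration vector (required by `"global"`).
#' @return an object of class `cm_fields`: list with `total`, `native_part`,
#'   `external_part` (`total = native_part + external_part`).
#' @export
local_fields <- function(network, state,
                         field_mode = c("none", "fixed_neurons", "global"),
                         w_ext = 0, xi_new = NULL) {
  field_mode <- match.arg(field_mode)
  if (length(state$s) != network$n_neurons)
    stop("state length does not match the network")
  h <- as.vector(network$J %*% state$s) / network$k
  if (field_mode == "none") {
    ext <- numeric(network$n_neurons)
    nat <- h
  } else if (field_mode == "fixed_neurons") {
    if (length(network$input_set) == 0L)
      stop("field_mode 'fixed_neurons' requires a wired input set")
    ext <- as.vector(network$J[, network$input_set, drop = FALSE] %*%
                       state$s[network$input_set]) / network$k
    nat <- h - ext
  } else {
    if (is.null(xi_new)) stop("field_mode 'global' requires xi_new")
    ext <- (w_ext / network$p) * xi_new
    nat <- h
    h <- h + ext
  }
  structure(list(total = h, native_part = nat, external_part = ext),
            class = "cm_fields")
}

#' One synchronous stochastic update of all non-clamped neurons
#'
#' Each non-fixed neuron aligns with the sign of its local field with
#' probability `P = 1 / (1 + exp(-2 * beta * |h_i|))` and anti-aligns
#' otherwise (heat-bath dynamics). At `beta -> 0` the alignment probability
#' is exactly 1/2; at large `beta` the update is effectively deterministic.
#' `sgn(0)` is taken to be the neuron's current sign, so a zero-field neuron
#' keeps or flips its state with probability 1/2 each -- a zero field carries
#' no information and this choice introduces no bias in either regime.
#'
#' @param state a `cm_state`.
#' @param fields a [local_fields()] result.
#' @return the updated `cm_state`.
#' @export
step_state <- function(state, fields) {
  h <- fields$total
  s <- state$s
  target <- sign(h)
  z <- target == 0
  if (any(z)) target[z] <- s[z]
  p_align <- 1 / (1 + exp(-2 * state$beta * abs(h)))
  aligned <- stats::runif(length(s)) < p_align
  new_s <- ifelse(aligned, target, -target)
  new_s[state$fixed] <- s[state$fixed]
  state$s <- new_s
  state
}

#' Overlap of a state with a stored pattern
#'
#' Absolute mean agreement between the instantaneous state and a +/-1
#' pattern, computed over neurons outside `excluded` (by convention the
#' clamped input subset is excluded from all order parameters).
#'
#' @param state a `cm_state` or a bare +/-1 vector.
#' @param pattern +/-1 vector of the same length.
#' @param excluded integer indices to leave out (may be empty).
#' @return overlap in `[0, 1]`: 1 = perfect recall (up to global sign flip),
#'   ~0 = no relation.
#' @export
overlap <- function(state, pattern, excluded = integer(0)) {
  s <- if (inherits(state, "cm_state")) state$s else state
  if (length(s) != length(pattern)) stop("state/pattern length mismatch")
  if (length(excluded) > 0L) {
    if (length(excluded) >= length(s))
      stop("cannot exclude every neuron from the overlap")
    s <- s[-excluded]
    pattern <- pattern[-excluded]
  }
  abs(mean(pattern * s))
}

#' Evolve the network for a number of iterations
#'
#' Repeatedly applies [local_fields()] and [step_state()], recording at every
#' iteration the overlap with each native memory, the overlap with the new
#' configuration, and the fraction of non-clamped neurons that changed state.
#' When `eps > 0` one Hebbian plasticity step ([hebbian_step()]) is
#' interleaved after each dynamics step and the updated network is returned.
#' `schedule = "asynchronous"` performs `N` random-order single-neuron
#' updates per iteration instead of one synchronous sweep (a sensitivity
#' check; the synchronous schedule is the default used by all protocols).
#'
#' @param network a `cm_network`.
#' @param patterns the pattern set (for the order parameters).
#' @param state a `cm_state`.
#' @param n_iterations number of iterations (>= 1).
#' @param field_mode,w_ext passed to [local_fields()].
#' @param eps Hebbian learning rate (0 = plasticity off).
#' @param schedule `"synchronous"` (default) or `"asynchronous"`.
#' @return an object of class `cm_trajectory`: list with `overlap_native`
#'   (`n_iterations x p` matrix), `overlap_new`, `flip_fraction` (vectors),
#'   the final `state`, and the (possibly updated) `network`.
#' @export
evolve <- function(network, patterns, state, n_iterations,
                   field_mode = c("none", "fixed_neurons", "global"),
                   w_ext = 0, eps = 0,
                   schedule = c("synchronous", "asynchronous")) {
  field_mode <- match.arg(field_mode)
  schedule <- match.arg(schedule)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  n_it <- as.integer(n_iterations)
  p <- patterns$p
  free <- !state$fixed
  n_free <- sum(free)
  m_nat <- matrix(NA_real_, n_it, p)
  m_new <- numeric(n_it)
  flips <- numeric(n_it)
  excl <- patterns$input_set
  for (t in seq_len(n_it)) {
    s_old <- state$s
    if (schedule == "synchronous") {
      f <- local_fields(network, state, field_mode, w_ext, patterns$new)
      state <- step_state(state, f)
    } else {
      state <- async_sweep(network, patterns, state, field_mode, w_ext)
    }
    if (eps > 0) network <- hebbian_step(network, state, eps)
    flips[t] <- sum(state$s[free] != s_old[free]) / n_free
    for (mu in seq_len(p))
      m_nat[t, mu] <- overlap(state, patterns$native[, mu], excl)
    m_new[t] <- overlap(state, patterns$new, excl)
  }
  structure(list(overlap_native = m_nat, overlap_new = m_new,
                 flip_fraction = flips, state = state, network = network),
            class = "cm_trajectory")
}

# one random-sequential sweep: N single-neuron heat-bath updates
async_sweep <- function(network, patterns, state, field_mode, w_ext) {
  n <- network$n_neurons
  beta <- state$beta
  s <- state$s
  ord <- sample.int(n)
  ext <- if (field_mode == "global") (w_ext / network$p) * patterns$new
         else numeric(n)
  Jt <- Matrix::t(network$J)  # column i of Jt = incoming weights of neuron i
  pj <- Jt@p; ij <- Jt@i; xj <- Jt@x
  for (i in ord) {
    if (state$fixed[i]) next
    idx <- if (pj[i + 1L] > pj[i]) (pj[i] + 1L):pj[i + 1L] else integer(0)
    h <- sum(xj[idx] * s[ij[idx] + 1L]) / network$k + ext[i]
    tgt <- if (h == 0) s[i] else sign(h)
    p_align <- 1 / (1 + exp(-2 * beta * abs(h)))
    s[i] <- if (stats::runif(1) < p_align) tgt else -tgt
  }
  state$s <- s
  state
}

#' Export a trajectory as tidy CSV plus JSON metadata
#'
#' Writes one row per (iteration, native memory) with the overlap series and
#' flip fractions, and a `<file>.json` sidecar carrying run parameters.
#'
#' @param trajectory a [evolve()] result.
#' @param file output CSV path.
#' @param metadata named list of run parameters stored in the sidecar.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(trajectory, file, metadata = list()) {
  stopifnot(inherits(trajectory, "cm_trajectory"))
  p <- ncol(trajectory$overlap_native)
  n_it <- nrow(trajectory$overlap_native)
  df <- data.frame(
    iteration = rep(seq_len(n_it), p),
    memory_index = rep(seq_len(p), each = n_it),
    overlap_native = as.vector(trajectory$overlap_native),
    overlap_new = rep(trajectory$overlap_new, p),
    flip_fraction = rep(trajectory$flip_fraction, p))
  utils::write.csv(df, file, row.names = FALSE)
  jsonlite::write_json(metadata, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}
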