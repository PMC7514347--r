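#' Critical temperature from the half-maximum of an order parameter
#'
#' The critical temperature is the point where the order parameter reaches
#' half of its observed maximum, found by linear interpolation between the
#' bracketing grid points. For a monotone-decreasing curve (an overlap order
#' parameter) the first downward crossing is used; for an increasing curve
#' (a flip-count stability curve) the first upward crossing. Using half the
#' *observed* maximum (rather than 1/2 of the theoretical ceiling) keeps the
#' estimator robust to imperfect low-temperature recall at high memory
#' loading.
#'
#' @param temperature ascending temperature grid (>= 3 points).
#' @param value order-parameter values on the grid.
#' @param direction `"decreasing"`, `"increasing"`, or `"auto"` (compare the
#'   curve ends).
#' @return an object of class `cm_transition_fit`: list with `t_c`, `slope`
#'   (the local finite-difference slope at the crossing), `method =
#'   "interpolation"`, `residual = NA`.
#' @export
tc_from_halfmax <- function(temperature, value,
                            direction = c("auto", "decreasing", "increasing")) {
  direction <- match.arg(direction)
  if (length(temperature) < 3L || length(value) != length(temperature))
    stop("need >= 3 (temperature, value) pairs")
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
  half <- max(value) / 2
  if (direction == "auto")
    direction <- if (value[1] >= value[length(value)]) "decreasing" else "increasing"
  if (direction == "decreasing") {
    i <- which(value[-length(value)] >= half & value[-1] < half)
  } else {
    i <- which(value[-length(value)] < half & value[-1] >= half)
  }
  if (length(i) == 0L)
    stop("order parameter never crosses its half-maximum: no transition in range")
  i <- i[1]
  t0 <- temperature[i]; t1 <- temperature[i + 1]
  v0 <- value[i]; v1 <- value[i + 1]
  t_c <- t0 + (half - v0) * (t1 - t0) / (v1 - v0)
  structure(list(t_c = t_c, slope = (v1 - v0) / (t1 - t0),
                 method = "interpolation", residual = NA_real_),
            class = "cm_transition_fit")
}

#' @export
print.cm_transition_fit <- function(x, ...) {
  cat(sprintf("Transition fit (%s): T_c = %.4f", x$method, x$t_c))
  if (!is.na(x$slope)) cat(sprintf(", slope = %.4g", x$slope))
  if (!is.na(x$residual)) cat(sprintf(", RSS = %.3g", x$residual))
  cat("\n")
  invisible(x)
}

#' Sigmoid fit of a stability (flip-count) curve
#'
#' Least-squares fit of `f(T) = 0.5 / (1 + exp(-(T - T_c) / mu))` to a
#' flip-fraction curve (normalised to `[0, 0.5]`: zero flips in the ordered
#' sub-critical regime, half the neurons flipping per iteration in the
#' disordered regime). Falls back to half-maximum interpolation (with a
#' warning) when the nonlinear fit does not converge.
#'
#' @param temperature ascending temperature grid.
#' @param flip_fraction mean flip fraction per temperature, in `[0, 0.5]`.
#' @return a `cm_transition_fit` with `t_c`, `slope` (the fitted width
#'   `mu`), `method = "sigmoid_fit"` and the residual sum of squares; on
#'   fallback `method = "interpolation_fallback"`.
#' @export
fit_sigmoid_stability <- function(temperature, flip_fraction) {
  if (any(flip_fraction < -1e-8 | flip_fraction > 0.5 + 1e-8))
    stop("flip_fraction must be normalised to [0, 0.5]")
  df <- data.frame(T = temperature, f = flip_fraction)
  start_tc <- tryCatch(
    tc_from_halfmax(temperature, flip_fraction, "increasing")$t_c,
    error = function(e) stats::median(temperature))
  start_mu <- diff(range(temperature)) / 10
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ 0.5 / (1 + exp(-(T - tc) / mu)), data = df,
                      start = list(tc = start_tc, mu = start_mu),
                      lower = c(tc = -Inf, mu = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("sigmoid fit did not converge; falling back to half-maximum interpolation")
    out <- tc_from_halfmax(temperature, flip_fraction, "increasing")
    out$method <- "interpolation_fallback"
    return(out)
  }
  cf <- stats::coef(fit)
  structure(list(t_c = unname(cf["tc"]), slope = unname(cf["mu"]),
                 method = "sigmoid_fit",
                 residual = sum(stats::residuals(fit)^2)),
            class = "cm_transition_fit")
}

#' Critical-temperature shift as a function of the learning rate
#'
#' For each learning rate runs a full learning sweep, fits stability sigmoids
#' to the pre- and post-learning flip curves, and reports the signed shift
#' `Delta T_c = T_c(pre) - T_c(post)` (negative when learning extends the
#' sub-critical regime to higher temperatures). The overall linearity of the
#' shift in the learning rate is summarised by a least-squares line.
#'
#' @param eps_values positive learning rates (the sweep is run once per
#'   value).
#' @inheritParams protocol_learn_sweep
#' @return a data.frame (`epsilon`, `tc_pre`, `tc_post`, `delta_tc`) with
#'   attributes `slope`, `intercept`, `r_squared` from the linear fit of
#'   `delta_tc ~ epsilon`.
#' @export
delta_tc_vs_epsilon <- function(eps_values, temperatures, n_neurons,
                                in_degree, p = 1, input_size, input_weight,
                                phases = c(pre = 100, learn = 100, post = 100),
                                rewire_prob = 0.1, realizations = 3, seed = 1) {
  stopifnot(length(eps_values) >= 1, all(eps_values > 0))
  rows <- lapply(eps_values, function(eps) {
    sw <- protocol_learn_sweep(temperatures, n_neurons, in_degree, p,
                               input_size = input_size,
                               input_weight = input_weight, eps = eps,
                               phases = phases, rewire_prob = rewire_prob,
                               realizations = realizations, seed = seed)
    sm <- summarize_sweep(sw)
    tc_pre <- fit_sigmoid_stability(sm$temperature, pmin(sm$flip_pre, 0.5))$t_c
    tc_post <- fit_sigmoid_stability(sm$temperature, pmin(sm$flip_post, 0.5))$t_c
    data.frame(epsilon = eps, tc_pre = tc_pre, tc_post = tc_post,
               delta_tc = tc_pre - tc_post)
  })
  out <- do.call(rbind, rows)
  if (nrow(out) >= 2) {
    lf <- stats::lm(delta_tc ~ epsilon, data = out)
    attr(out, "slope") <- unname(stats::coef(lf)[2])
    attr(out, "intercept") <- unname(stats::coef(lf)[1])
    attr(out, "r_squared") <- summary(lf)$r.squared
  }
  out
}

#' Consolidation phase map over memory loading and temperature
#'
#' For each number of pre-loaded native memories `p` runs a learning sweep
#' and classifies, per temperature, pre-learning native stability
#' (`m_native >= threshold`) and post-learning consolidation of the new
#' configuration (`m_new >= threshold`). The pre-learning critical line is
#' the first temperature at which native stability is lost.
#'
#' @param p_values numbers of native memories to pre-load.
#' @inheritParams protocol_learn_sweep
#' @param threshold stability threshold (default 0.45).
#' @return a data.frame (`p`, `alpha` = p/in_degree, `temperature`,
#'   `m_native_pre`, `m_new_post`, `native_stable`, `consolidated`,
#'   `above_nominal_capacity`) with attribute `critical_line` (per-`p` first
#'   unstable temperature).
#' @export
capacity_diagram <- function(p_values, temperatures, n_neurons, in_degree,
                             input_size, input_weight = 3, eps = 0.1,
                             phases = c(pre = 100, learn = 500, post = 100),
                             rewire_prob = 0.1, realizations = 5,
                             threshold = 0.45, seed = 1) {
  stopifnot(all(p_values >= 1))
  out <- list(); cl <- list()
  for (p in p_values) {
    sw <- protocol_learn_sweep(temperatures, n_neurons, in_degree, p = p,
                               input_size = input_size,
                               input_weight = input_weight, eps = eps,
                               phases = phases, rewire_prob = rewire_prob,
                               realizations = realizations, seed = seed)
    sm <- summarize_sweep(sw)
    stab <- sm$m_native_pre >= threshold
    cons <- sm$m_new_post >= threshold
    first_unstable <- if (any(!stab)) sm$temperature[which(!stab)[1]] else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      p = p, alpha = p / in_degree, temperature = sm$temperature,
      m_native_pre = sm$m_native_pre, m_new_post = sm$m_new_post,
      native_stable = stab, consolidated = cons,
      above_nominal_capacity = p > 0.14 * in_degree)
    cl[[length(cl) + 1L]] <- data.frame(p = p, alpha = p / in_degree,
                                        t_critical = first_unstable)
  }
  res <- do.call(rbind, out)
  attr(res, "critical_line") <- do.call(rbind, cl)
  res
}

# deterministic (T = 0) recall test: do all stored patterns stay above the
# overlap threshold after sign-alignment relaxation? Sequential site updates
# are used here: they descend the energy and converge to a fixed point,
# whereas fully parallel deterministic updates on symmetric couplings can
# enter period-2 cycles that spuriously destroy recall.
recall_ok <- function(X, p, recall_threshold, n_relax) {
  Xp <- X[, seq_len(p), drop = FALSE]
  n <- nrow(Xp)
  J <- tcrossprod(Xp) / p
  diag(J) <- 0
  for (mu in seq_len(p)) {
    s <- Xp[, mu]
    h <- as.vector(J %*% s)
    for (it in seq_len(n_relax)) {
      changed <- FALSE
      for (i in seq_len(n)) {
        ns <- if (h[i] == 0) s[i] else sign(h[i])
        if (ns != s[i]) {
          h <- h + J[, i] * (ns - s[i])
          s[i] <- ns
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (abs(mean(Xp[, mu] * s)) < recall_threshold) return(FALSE)
  }
  TRUE
}

#' Maximal memory loading of the fully connected network at T = 0
#'
#' Classic storage-capacity check: patterns are embedded by the
#' outer-product rule in a fully connected network (`k = N - 1`, no
#' self-couplings) and relaxed with deterministic sign-alignment updates (the
#' zero-temperature limit of the heat-bath rule, implemented directly to
#' avoid overflowing the exponential), applied sequentially so relaxation
#' descends the energy to a fixed point. A loading `p` passes when relaxation
#' started from each stored pattern keeps its overlap at or above
#' `recall_threshold`; the largest passing `p` is located by bisection at
#' resolution `max(1, N/200)` and averaged over seeds.
#'
#' @param n_neurons network size.
#' @param n_seeds number of independent pattern draws.
#' @param recall_threshold overlap defining successful recall (default 0.9).
#' @param n_relax maximum relaxation sweeps per test (default 30).
#' @param p_hi_frac upper bracket for the bisection, as a fraction of N.
#' @param seed base seed; seed `s` uses `seed + s`.
#' @return list with `alpha_max` (mean p_max / N), `p_max` (per-seed vector),
#'   `n_neurons`.
#' @export
hopfield_capacity_check <- function(n_neurons, n_seeds = 10,
                                    recall_threshold = 0.9, n_relax = 30,
                                    p_hi_frac = 0.3, seed = 1) {
  n <- as.integer(n_neurons)
  dp <- max(1L, as.integer(round(n / 200)))
  p_hi <- max(2L, as.integer(round(p_hi_frac * n)))
  p_max <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s)
    X <- matrix(sample(c(-1, 1), n * p_hi, replace = TRUE), n, p_hi)
    lo <- 1L; hi <- p_hi
    if (recall_ok(X, hi, recall_threshold, n_relax)) {
      p_max[s] <- hi
      next
    }
    while (hi - lo > dp) {
      mid <- as.integer((lo + hi) %/% 2)
      if (recall_ok(X, mid, recall_threshold, n_relax)) lo <- mid else hi <- mid
    }
    p_max[s] <- lo
  }
  list(alpha_max = mean(p_max) / n, p_max = p_max, n_neurons = n)
}
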