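# Registry of numeric operations available to the propagation machinery.
# Every function is vectorized elementwise over its arguments so the
# Monte-Carlo driver can evaluate 1e6 draws in one call.
.mb_ops <- new.env(parent = emptyenv())

register_op <- function(name, fn) assign(name, fn, envir = .mb_ops)

local({
  register_op("basalt_fraction",
              function(a, b, c) (a - b) / (c - b))
  # the same ratio with the shared baseline split into two independent
  # occurrences (a - b1)/(c - b2); the Monte-Carlo counterpart of the
  # independent-occurrence analytic convention
  register_op("ratio_of_differences_split",
              function(a, b1, b2, c) (a - b1) / (c - b2))
  register_op("soil_mass",
              function(depth, area, rho) depth * area * rho * (10000 / area))
  register_op("basalt_mass",
              function(m_soil, p) {
                out <- m_soil * p / (1 - p)
                out[p >= 1] <- NaN  # precondition p_basalt < 1
                out
              })
  register_op("depth_fraction",
              function(m_layer, m_total) m_layer / m_total)
  register_op("expected_cation",
              function(cb, cs, p) cb * p + (1 - p) * cs)
  register_op("weathered_cation",
              function(expected, observed) expected - observed)
  register_op("weathered_proportion",
              function(w, cb, p) {
                out <- w / (cb * p)
                out[cb * p <= 0] <- NaN  # precondition: positive basalt pool
                out
              })
  register_op("cdr_potential",
              function(p_ca, p_mg, ca_mg_kg, mg_mg_kg, m_applied)
                cdr_potential_num(p_ca, p_mg, ca_mg_kg, mg_mg_kg, m_applied))
  # full per-cation estimator: tracer means + cation means -> loss proportion;
  # shared terms are genuinely shared, so the plain delta method on this
  # composition is the statistically faithful propagation
  register_op("loss_fraction",
              function(ti_treated, ti_soil, ti_basalt,
                       obs, conc_soil, conc_basalt) {
                p <- (ti_treated - ti_soil) / (ti_basalt - ti_soil)
                expd <- conc_basalt * p + (1 - p) * conc_soil
                out <- (expd - obs) / (conc_basalt * p)
                out[conc_basalt * p <= 0] <- NaN
                out
              })
})

#' Names of operations registered for uncertainty propagation
#' @return Character vector of operation names usable with
#'   [propagate_through()] and [monte_carlo()].
#' @export
propagation_ops <- function() sort(ls(.mb_ops))

get_op <- function(op_name) {
  if (!exists(op_name, envir = .mb_ops, inherits = FALSE))
    stop("unknown operation '", op_name, "'; see propagation_ops()",
         call. = FALSE)
  get(op_name, envir = .mb_ops)
}

new_propagation_result <- function(value, sd, method,
                                   n_draws = NULL, seed = NULL) {
  structure(list(value = value, sd = sd, method = method,
                 n_draws = n_draws, seed = seed),
            class = c("propagation_result", "mq"))
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("<propagated:", x$method, "> ", format.mq(x), "\n", sep = "")
  invisible(x)
}

#' First-order SD of (a - b)/(c - b)
#'
#' The mixing-ratio shape of the basalt-fraction estimate, with closed-form
#' first-order ("standard rules") propagation. The baseline `b` appears in
#' both numerator and denominator; by default its two occurrences are treated
#' as independent — relative variances of numerator and denominator add —
#' which is the convention that reproduces published mixing-ratio SDs of this
#' kind. The statistically correlated treatment (one shared `b`) is available
#' with `correlated_b = TRUE` for sensitivity analysis.
#'
#' @param a,b,c [mq()] quantities (plain numbers are taken as exact).
#' @param correlated_b Treat the shared baseline as a single random variable?
#' @return A `propagation_result` (value, sd, method = "analytic").
#' @examples
#' propagate_ratio_of_differences(mq(3417, 279), mq(2693, 196), mq(10899, 420))
#' @export
propagate_ratio_of_differences <- function(a, b, c, correlated_b = FALSE) {
  a <- as_mq(a); b <- as_mq(b); c <- as_mq(c)
  num <- a$value - b$value
  den <- c$value - b$value
  if (abs(den) < .Machine$double.eps * max(abs(c$value), abs(b$value), 1))
    stop("degenerate denominator: c - b is (numerically) zero", call. = FALSE)
  v <- num / den
  if (correlated_b) {
    g <- c(1 / den, (a$value - c$value) / den^2, -num / den^2)  # d/da, d/db, d/dc
    s <- sqrt(sum((g * c(a$sd, b$sd, c$sd))^2))
  } else {
    var_num <- a$sd^2 + b$sd^2
    var_den <- c$sd^2 + b$sd^2
    s <- abs(v) * sqrt(var_num / num^2 + var_den / den^2)
  }
  new_propagation_result(v, s, "analytic")
}

#' Delta-method propagation through a registered operation
#'
#' First-order Gaussian error propagation: the output SD is
#' `sqrt(sum((df/dx_i)^2 sd_i^2))` with partial derivatives evaluated by
#' central differences (step `max(1e-6 |x|, 1e-9)`). The value is the plain
#' operation applied to the input values, exactly. Inputs are assumed
#' independent (no covariance information is carried).
#'
#' @param op_name One of [propagation_ops()].
#' @param inputs List of [mq()] (or plain numbers, taken as exact), in the
#'   operation's argument order.
#' @return A `propagation_result` with method `"analytic"`.
#' @export
propagate_through <- function(op_name, inputs) {
  fn <- get_op(op_name)
  if (length(inputs) != length(formals(fn)))
    stop("operation '", op_name, "' takes ", length(formals(fn)),
         " inputs, got ", length(inputs), call. = FALSE)
  inputs <- lapply(inputs, as_mq)
  x <- vapply(inputs, function(q) q$value, numeric(1))
  s <- vapply(inputs, function(q) q$sd, numeric(1))
  v <- do.call(fn, as.list(x))
  if (!is.finite(v)) stop("operation value is not finite at the input means",
                          call. = FALSE)
  grad <- numeric(length(x))
  for (i in seq_along(x)) {
    if (s[i] == 0) next  # derivative irrelevant for exact inputs
    h <- max(1e-6 * abs(x[i]), 1e-9)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    grad[i] <- (do.call(fn, as.list(xp)) - do.call(fn, as.list(xm))) / (2 * h)
    if (!is.finite(grad[i]))
      stop("non-finite partial derivative of '", op_name,
           "' with respect to input ", i, call. = FALSE)
  }
  new_propagation_result(v, sqrt(sum((grad * s)^2)), "analytic")
}

#' Monte-Carlo propagation oracle
#'
#' Draws independent normal deviates for every input, applies the operation,
#' and returns the sample mean and SD. Deterministic given `seed`. Serves as
#' the independent check on the first-order analytic propagation.
#'
#' @inheritParams propagate_through
#' @param n_draws Number of draws, at least 1000.
#' @param seed Integer RNG seed (local to the call; the caller's RNG state is
#'   untouched).
#' @param truncate_at_zero Resample-free truncation: draws are censored at 0
#'   (physical lower bound for concentrations). Default FALSE.
#' @return A `propagation_result` with method `"monte_carlo"`, the draw count
#'   and the seed. Errors if the operation yields non-finite results on more
#'   than 1% of draws.
#' @export
monte_carlo <- function(op_name, inputs, n_draws = 1e5, seed = 1,
                        truncate_at_zero = FALSE) {
  if (n_draws < 1000) stop("n_draws must be at least 1000", call. = FALSE)
  fn <- get_op(op_name)
  if (length(inputs) != length(formals(fn)))
    stop("operation '", op_name, "' takes ", length(formals(fn)),
         " inputs, got ", length(inputs), call. = FALSE)
  inputs <- lapply(inputs, as_mq)
  draws <- withr_seed(seed, {
    lapply(inputs, function(q) {
      d <- if (q$sd == 0) rep.int(q$value, n_draws)
           else stats::rnorm(n_draws, q$value, q$sd)
      if (truncate_at_zero) d[d < 0] <- 0
      d
    })
  })
  out <- do.call(fn, draws)
  bad <- !is.finite(out)
  if (mean(bad) > 0.01)
    stop("operation '", op_name, "' failed (non-finite) on ",
         round(100 * mean(bad), 1),
         "% of draws; an input precondition (e.g. p_basalt < 1, ",
         "nonzero tracer contrast) is violated too often", call. = FALSE)
  out <- out[!bad]
  new_propagation_result(mean(out), stats::sd(out), "monte_carlo",
                         n_draws = n_draws, seed = seed)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
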