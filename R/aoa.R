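#' Configuration for the Archimedes optimization algorithm
#'
#' The algorithm evolves a population of "materials", each carrying a
#' position, a density, a volume and an acceleration. A transfer factor
#' rising from exp(-1) to 1 over the run switches the update from global
#' exploration (collisions with a random material) to local exploitation
#' (attraction to the incumbent best).
#'
#' @param pop population size (>= 2).
#' @param iters maximum number of iterations.
#' @param C1,C2,C3,C4 the four fixed constants of the position update;
#'   defaults 2, 6, 1, 2.
#' @param u,l acceleration-normalization range parameters (defaults 0.9 and
#'   0.1, giving normalized accelerations in `[0.1, 1.0]`).
#' @param seed optional integer seed; when given, the whole run is
#'   bitwise reproducible.
#' @param exploit_form `"canonical"` uses the attractor `T*x_best - x_i`
#'   in the exploitation step; `"as_printed"` uses `T*(x_best - x_i)`.
#' @param acc_dispersion apply the source algorithm's per-material uniform
#'   dispersion factor in the acceleration denominator (default TRUE; see
#'   [update_acceleration()]).
#' @return a list of class `aoa_config`.
#' @export
aoa_config <- function(pop = 30L, iters = 500L, C1 = 2, C2 = 6, C3 = 1,
                       C4 = 2, u = 0.9, l = 0.1, seed = NULL,
                       exploit_form = c("canonical", "as_printed"),
                       acc_dispersion = TRUE) {
  stopifnot(pop >= 2, iters >= 0, C1 > 0, C2 > 0, C3 > 0, C4 > 0,
            u > l, l > 0)
  structure(list(pop = as.integer(pop), iters = as.integer(iters),
                 C1 = C1, C2 = C2, C3 = C3, C4 = C4, u = u, l = l,
                 seed = seed, exploit_form = match.arg(exploit_form),
                 acc_dispersion = isTRUE(acc_dispersion)),
            class = "aoa_config")
}

#' Transfer factor
#'
#' `exp((t - t_max)/t_max)`: rises monotonically from about exp(-1) to 1,
#' moving the search from exploration (TF <= 0.5) to exploitation.
#'
#' @param t current iteration.
#' @param t_max maximum iteration (> 0).
#' @return a scalar in `(0, 1]`.
#' @export
transfer_factor <- function(t, t_max) {
  if (t_max <= 0) stop("t_max must be positive")
  exp((t - t_max) / t_max)
}

#' Density factor
#'
#' `exp((t_max - t)/t_max) - t/t_max`: decreases monotonically from e at
#' t = 0 to 0 at t = t_max, shrinking step sizes as the run proceeds.
#'
#' @inheritParams transfer_factor
#' @return a non-negative scalar for `t <= t_max`.
#' @export
density_factor <- function(t, t_max) {
  if (t_max <= 0) stop("t_max must be positive")
  exp((t_max - t) / t_max) - t / t_max
}

#' Initialize an AOA population
#'
#' Positions are uniform inside the bounds, densities and volumes uniform in
#' (0,1), accelerations uniform within the bounds scale; the incumbent best
#' is the fittest initial material. Draws come from the active RNG stream.
#'
#' @param objective function mapping a length-`d` numeric vector to a scalar.
#' @param lower,upper per-dimension bounds.
#' @param n population size.
#' @param positions optional `n x d` matrix of pre-made initial positions
#'   (used by the improved variant's chaotic initializer).
#' @return a list of class `aoa_population` with elements `X`, `den`, `vol`,
#'   `acc`, `fit`, `best`, `lower`, `upper`.
#' @export
initialize_population <- function(objective, lower, upper, n,
                                  positions = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), n >= 1)
  if (is.null(positions)) {
    X <- matrix(stats::runif(n * d), n, d)
    X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  } else {
    X <- as.matrix(positions)
    stopifnot(nrow(X) == n, ncol(X) == d)
  }
  den <- stats::runif(n)
  vol <- stats::runif(n)
  acc <- matrix(stats::runif(n * d), n, d)
  acc <- sweep(sweep(acc, 2, upper - lower, "*"), 2, lower, "+")
  fit <- eval_rows(objective, X)
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1]
    stop(sprintf("objective is not finite at initial point (%s)",
                 paste(signif(X[bad, ], 6), collapse = ", ")))
  }
  b <- which.min(fit)
  structure(list(X = X, den = den, vol = vol, acc = acc, fit = fit,
                 best = list(x = X[b, ], den = den[b], vol = vol[b],
                             acc = acc[b, ], fit = fit[b]),
                 lower = lower, upper = upper),
            class = "aoa_population")
}

#' @export
print.aoa_population <- function(x, ...) {
  cat(sprintf("<aoa_population> n = %d, d = %d, best fitness = %g\n",
              nrow(x$X), ncol(x$X), x$best$fit))
  invisible(x)
}

#' Density and volume update
#'
#' Moves each material's density and volume a uniform random fraction of the
#' way toward the incumbent best's, one fresh draw per material per quantity.
#'
#' @param pop an `aoa_population`.
#' @return the updated population.
#' @export
update_density_volume <- function(pop) {
  n <- length(pop$den)
  pop$den <- pop$den + stats::runif(n) * (pop$best$den - pop$den)
  pop$vol <- pop$vol + stats::runif(n) * (pop$best$vol - pop$vol)
  pop
}

#' Acceleration update
#'
#' Exploration (TF <= 0.5): each material collides with a uniformly random
#' material `mr` and takes acceleration `(den_mr + vol_mr * acc_mr) /
#' (den_i * vol_i)`. Exploitation (TF > 0.5): the incumbent best replaces
#' the random material. The denominator is floored at 1e-12.
#'
#' With `dispersion = TRUE` (the default used by the optimizers) the
#' denominator carries an extra per-material uniform factor, as in the
#' source algorithm's reference implementation. The factor spreads the
#' raw accelerations over orders of magnitude, so after min-max
#' normalization most materials sit near the lower bound `l` and late
#' iterations take small, steadily contracting steps — the behaviour that
#' produces the extreme convergence this family of optimizers is known
#' for. With `dispersion = FALSE` the update is the plain textbook
#' arithmetic.
#'
#' @param pop an `aoa_population` whose densities/volumes are updated.
#' @param TF transfer factor for the current iteration.
#' @param dispersion apply the uniform denominator dispersion factor.
#' @return the updated population.
#' @export
update_acceleration <- function(pop, TF, dispersion = TRUE) {
  n <- length(pop$den)
  scale <- if (dispersion) stats::runif(n) else rep(1, n)
  denom <- pmax(scale * pop$den * pop$vol, 1e-12)
  if (TF <= 0.5) {
    mr <- sample.int(n, n, replace = TRUE)
    num <- pop$den[mr] + pop$vol[mr] * pop$acc[mr, , drop = FALSE]
  } else {
    vec <- pop$best$den + pop$best$vol * pop$best$acc
    num <- matrix(vec, n, length(vec), byrow = TRUE)
  }
  pop$acc <- num / denom
  pop
}

#' Min-max normalization of accelerations
#'
#' `acc_norm = u * (acc - min(acc)) / (max(acc) - min(acc)) + l`, with the
#' min/max taken over the whole population. If all accelerations are equal
#' the output degenerates to `l` everywhere. The normalized matrix both
#' feeds the position update and replaces the stored accelerations for the
#' next iteration (as in the source algorithm's reference implementation,
#' which keeps accelerations on the bounded `[l, u + l]` scale between
#' iterations).
#'
#' @param pop an `aoa_population`.
#' @param u,l normalization range parameters.
#' @return the population with an added `acc_norm` matrix in `[l, u + l]`
#'   (also copied into `acc`).
#' @export
normalize_acceleration <- function(pop, u = 0.9, l = 0.1) {
  mn <- min(pop$acc)
  mx <- max(pop$acc)
  if (mx == mn) {
    pop$acc_norm <- matrix(l, nrow(pop$acc), ncol(pop$acc))
  } else {
    pop$acc_norm <- u * (pop$acc - mn) / (mx - mn) + l
  }
  pop$acc <- pop$acc_norm
  pop
}

#' Position update, re-evaluation and incumbent refresh
#'
#' Exploration (TF <= 0.5): `x_i <- x_i + C1 * rand * acc_norm_i * d *
#' (x_rand - x_i)` with `x_rand` a random material. Exploitation:
#' `x_i <- x_best + F * C2 * rand * acc_norm_i * d * (T * x_best - x_i)`
#' with `T = C3 * TF` and direction factor `F = +1` if `2*rand - C4 <= 0.5`,
#' else `-1`. Positions are clipped to the bounds, fitness re-evaluated, and
#' the incumbent updated if beaten.
#'
#' @param pop an `aoa_population` with `acc_norm` present.
#' @param TF transfer factor.
#' @param dfac density factor.
#' @param config an `aoa_config`.
#' @param objective the objective function.
#' @return the updated population.
#' @export
update_positions <- function(pop, TF, dfac, config, objective) {
  n <- nrow(pop$X)
  d <- ncol(pop$X)
  R <- matrix(stats::runif(n * d), n, d)
  if (TF <= 0.5) {
    mr <- sample.int(n, n, replace = TRUE)
    Xnew <- pop$X + config$C1 * R * pop$acc_norm * dfac *
      (pop$X[mr, , drop = FALSE] - pop$X)
  } else {
    p <- 2 * stats::runif(n) - config$C4
    Fdir <- ifelse(p <= 0.5, 1, -1)
    Tt <- config$C3 * TF
    Xb <- matrix(pop$best$x, n, d, byrow = TRUE)
    attract <- if (config$exploit_form == "canonical") {
      Tt * Xb - pop$X
    } else {
      Tt * (Xb - pop$X)
    }
    Xnew <- Xb + Fdir * config$C2 * R * pop$acc_norm * dfac * attract
  }
  Xnew <- clip_bounds(Xnew, pop$lower, pop$upper)
  fit <- eval_rows(objective, Xnew)
  pop$X <- Xnew
  pop$fit <- fit
  b <- which.min(fit)
  if (is.finite(fit[b]) && fit[b] < pop$best$fit) {
    pop$best <- list(x = Xnew[b, ], den = pop$den[b], vol = pop$vol[b],
                     acc = pop$acc[b, ], fit = fit[b])
  }
  pop
}

# One full AOA iteration (density/volume, acceleration, normalization,
# position update). Shared by the baseline and improved optimizers.
aoa_iterate <- function(pop, t, config, objective) {
  TF <- transfer_factor(t, config$iters)
  dfac <- density_factor(t, config$iters)
  pop <- update_density_volume(pop)
  pop <- update_acceleration(pop, TF, dispersion = config$acc_dispersion)
  pop <- normalize_acceleration(pop, config$u, config$l)
  update_positions(pop, TF, dfac, config, objective)
}

#' Run the Archimedes optimization algorithm
#'
#' Minimizes `objective` over the box `[lower, upper]`.
#'
#' @param objective function from a length-`d` vector to a scalar, or a
#'   `benchmark_function` (whose bounds then serve as defaults).
#' @param lower,upper per-dimension bounds (taken from the benchmark
#'   function if omitted).
#' @param config an `aoa_config`.
#' @return an `optim_result`: list with `best_par`, `best_value`, `trace`
#'   (best-so-far fitness after initialization and after each iteration,
#'   length `iters + 1`), `evals`, and the config used.
#' @examples
#' res <- aoa_optimize(benchmark_function("F1", dimension = 2),
#'                     config = aoa_config(pop = 20, iters = 100, seed = 1))
#' res$best_value
#' @export
aoa_optimize <- function(objective, lower = NULL, upper = NULL,
                         config = aoa_config()) {
  obj <- resolve_objective(objective, lower, upper)
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(obj$fn, obj$lower, obj$upper, config$pop)
  trace <- numeric(config$iters + 1)
  trace[1] <- pop$best$fit
  if (config$iters > 0) {
    for (t in seq_len(config$iters)) {
      pop <- aoa_iterate(pop, t, config, obj$fn)
      trace[t + 1] <- pop$best$fit
    }
  }
  optim_result("aoa", pop$best$x, pop$best$fit, trace, config)
}

# Accept either a bare function (bounds required) or a benchmark_function.
resolve_objective <- function(objective, lower, upper) {
  if (inherits(objective, "benchmark_function")) {
    list(fn = objective$fn,
         lower = if (is.null(lower)) objective$lower else lower,
         upper = if (is.null(upper)) objective$upper else upper)
  } else {
    if (is.null(lower) || is.null(upper)) {
      stop("lower/upper bounds are required for a plain objective function")
    }
    list(fn = objective, lower = lower, upper = upper)
  }
}

optim_result <- function(algorithm, par, value, trace, config) {
  structure(list(algorithm = algorithm, best_par = par, best_value = value,
                 trace = trace, evals = NA_integer_, config = config),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("<optim_result> %s: best value %.6g after %d iterations\n",
              x$algorithm, x$best_value, length(x$trace) - 1))
  invisible(x)
}
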