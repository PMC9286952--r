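#' Configuration for the improved Archimedes optimization algorithm
#'
#' Extends [aoa_config()] with the three improvement strategies: sine-chaos
#' population initialization, opposition-based ("reverse learning")
#' candidate generation with best-of-union selection, and per-iteration
#' Gaussian mutation of the incumbent accepted only on strict improvement
#' ("superior selection").
#'
#' @inheritParams aoa_config
#' @param mutation_probability probability `p` that an improving mutated
#'   incumbent is accepted (default 0.5).
#' @param gaussian_sigma spread of the multiplicative Gaussian mutation
#'   (default 1, i.e. standard normal).
#' @param chaos_burn_in iterations of the chaotic map discarded before the
#'   stream is used (default 100).
#' @return a list of class `iaoa_config` (also inherits `aoa_config`).
#' @export
iaoa_config <- function(pop = 30L, iters = 500L, C1 = 2, C2 = 6, C3 = 1,
                        C4 = 2, u = 0.9, l = 0.1, seed = NULL,
                        exploit_form = c("canonical", "as_printed"),
                        mutation_probability = 0.5, gaussian_sigma = 1,
                        chaos_burn_in = 100L) {
  stopifnot(mutation_probability >= 0, mutation_probability <= 1,
            gaussian_sigma > 0, chaos_burn_in >= 0)
  cfg <- aoa_config(pop, iters, C1, C2, C3, C4, u, l, seed, exploit_form)
  cfg$mutation_probability <- mutation_probability
  cfg$gaussian_sigma <- gaussian_sigma
  cfg$chaos_burn_in <- as.integer(chaos_burn_in)
  class(cfg) <- c("iaoa_config", "aoa_config")
  cfg
}

#' Sine chaotic sequence
#'
#' Iterates the infinite-collapse sine map `x_{t+1} = sin(2 / x_t)` on
#' `[-1,1] \ {0}`. An iterate that lands exactly on 0 (a measure-zero event)
#' is replaced by a fresh uniform draw from the active RNG stream so the
#' sequence can continue.
#'
#' @param x0 starting value in `[-1, 1]`, nonzero.
#' @param length number of iterates to return (excluding `x0`).
#' @param burn_in iterates discarded before recording starts.
#' @return numeric vector of `length` values in `[-1, 1]`.
#' @export
sine_chaos_sequence <- function(x0, length, burn_in = 0L) {
  if (x0 == 0) stop("x0 must be nonzero")
  if (abs(x0) > 1) stop("x0 must lie in [-1, 1]")
  total <- burn_in + length
  out <- numeric(length)
  x <- x0
  for (i in seq_len(total)) {
    x <- sin(2 / x)
    if (x == 0) x <- stats::runif(1, -1, 1)
    if (i > burn_in) out[i - burn_in] <- x
  }
  out
}

#' Chaotic population initialization
#'
#' Generates an `n x d` position matrix by running one independent sine-chaos
#' stream per dimension (each seeded from the active RNG stream with a
#' burn-in) and mapping the chaotic values affinely from `[-1, 1]` onto
#' `[lower_j, upper_j]`.
#'
#' @param n population size.
#' @param lower,upper per-dimension bounds.
#' @param burn_in chaotic burn-in per stream (default 100).
#' @return an `n x d` matrix of positions inside the bounds.
#' @export
chaos_initialize <- function(n, lower, upper, burn_in = 100L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower), n >= 1)
  X <- matrix(0, n, d)
  for (j in seq_len(d)) {
    x0 <- 0
    while (x0 == 0) x0 <- stats::runif(1, -1, 1)
    v <- sine_chaos_sequence(x0, n, burn_in = burn_in)
    X[, j] <- lower[j] + (v + 1) / 2 * (upper[j] - lower[j])
  }
  X
}

#' Opposition-based population
#'
#' Reflects each candidate through the population's dynamic boundary:
#' `X*_ij = Xmin_j + Xmax_j - X_ij`, where `Xmin_j`/`Xmax_j` are the
#' per-dimension minimum/maximum of the current population.
#'
#' @param X an `n x d` position matrix.
#' @return the reflected `n x d` matrix.
#' @export
opposition_population <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  sweep(-X, 2, mn + mx, "+")
}

#' Best-of-union selection
#'
#' Evaluates the original and opposition populations and keeps the `n`
#' fittest rows of the `2n` union; ties are broken by position in the
#' concatenation (originals before opposites).
#'
#' @param X,X_star two `n x d` position matrices.
#' @param objective the objective function.
#' @return list with `X` (the selected `n x d` matrix) and `fit` (its
#'   fitness values).
#' @export
merge_select <- function(X, X_star, objective) {
  U <- rbind(as.matrix(X), as.matrix(X_star))
  fit <- eval_rows(objective, U)
  keep <- order(fit)[seq_len(nrow(X))]
  list(X = U[keep, , drop = FALSE], fit = fit[keep])
}

#' Gaussian elite mutation with superior selection
#'
#' Perturbs the incumbent multiplicatively, `candidate = best * (1 +
#' Gauss(sigma))` with one independent draw per dimension, and accepts it
#' only if a uniform draw falls below `p` *and* the candidate strictly
#' improves the objective (minimization). Note the multiplicative form
#' leaves an exactly-zero incumbent fixed.
#'
#' @param best_position,best_fitness the incumbent and its objective value.
#' @param objective the objective function.
#' @param p superior-selection probability.
#' @param sigma Gaussian spread.
#' @param lower,upper optional bounds to clip the candidate to.
#' @return list with `x`, `fit` and logical `accepted`.
#' @export
gaussian_elite_mutation <- function(best_position, best_fitness, objective,
                                    p = 0.5, sigma = 1,
                                    lower = NULL, upper = NULL) {
  g <- stats::rnorm(length(best_position), 0, sigma)
  cand <- best_position * (1 + g)
  if (!is.null(lower)) {
    cand <- pmin(pmax(cand, lower), upper)
  }
  r1 <- stats::runif(1)
  fc <- objective(cand)
  if (r1 < p && is.finite(fc) && fc < best_fitness) {
    list(x = cand, fit = fc, accepted = TRUE)
  } else {
    list(x = best_position, fit = best_fitness, accepted = FALSE)
  }
}

#' Run the improved Archimedes optimization algorithm
#'
#' Initializes the population with the sine-chaos map, doubles it by
#' opposition-based reflection and keeps the fitter half, then runs the
#' standard AOA update cycle with a Gaussian elite mutation of the incumbent
#' after every iteration.
#'
#' @inheritParams aoa_optimize
#' @param config an [iaoa_config()].
#' @return an `optim_result` (see [aoa_optimize()]).
#' @examples
#' res <- iaoa_optimize(benchmark_function("F12"),
#'                      config = iaoa_config(pop = 20, iters = 100, seed = 1))
#' res$best_value
#' @export
iaoa_optimize <- function(objective, lower = NULL, upper = NULL,
                          config = iaoa_config()) {
  obj <- resolve_objective(objective, lower, upper)
  if (!is.null(config$seed)) set.seed(config$seed)
  Xc <- chaos_initialize(config$pop, obj$lower, obj$upper,
                         burn_in = config$chaos_burn_in)
  Xo <- opposition_population(Xc)
  Xo <- clip_bounds(Xo, obj$lower, obj$upper)
  sel <- merge_select(Xc, Xo, obj$fn)
  pop <- initialize_population(obj$fn, obj$lower, obj$upper, config$pop,
                               positions = sel$X)
  trace <- numeric(config$iters + 1)
  trace[1] <- pop$best$fit
  if (config$iters > 0) {
    for (t in seq_len(config$iters)) {
      pop <- aoa_iterate(pop, t, config, obj$fn)
      mut <- gaussian_elite_mutation(pop$best$x, pop$best$fit, obj$fn,
                                     p = config$mutation_probability,
                                     sigma = config$gaussian_sigma,
                                     lower = obj$lower, upper = obj$upper)
      if (mut$accepted) {
        pop$best$x <- mut$x
        pop$best$fit <- mut$fit
      }
      trace[t + 1] <- pop$best$fit
    }
  }
  optim_result("iaoa", pop$best$x, pop$best$fit, trace, config)
}
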