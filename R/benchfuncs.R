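#' Benchmark objective function registry
#'
#' Thirteen classical minimization test problems used to compare
#' metaheuristics: five unimodal functions (F1-F5), five high-dimensional
#' multimodal functions (F6-F10), and three fixed-dimension multimodal
#' functions (F11-F13). Each entry carries the canonical benchmark-suite
#' definition, box bounds, dimension, and known global minimum.
#'
#' The registry follows the canonical suite conventions: Sphere on
#' \[-100,100\], Schwefel 2.22 on \[-10,10\], Schwefel 1.2 and 2.21 on
#' \[-100,100\], noisy Quartic on \[-1.28,1.28\], Rastrigin on \[-5.12,5.12\],
#' Ackley on \[-32,32\], Griewank on \[-600,600\], Penalized 1/2 on
#' \[-50,50\], the 4-parameter Kowalik least-squares problem on \[-5,5\],
#' the six-hump camel on \[-5,5\]^2, and Branin on \[-5,10\]x\[0,15\].
#' F5 adds uniform `[0,1)` noise drawn from the active RNG stream per
#' evaluation; `noisy = FALSE` disables it.
#'
#' @param name one of `"F1".."F13"` or a canonical alias such as
#'   `"sphere"`, `"rastrigin"`, `"ackley"`, `"griewank"`, `"kowalik"`,
#'   `"sixhump"`, `"branin"`.
#' @param dimension optional override of the dimension for F1-F10
#'   (default 30). Fixed-dimension functions ignore it.
#' @param noisy logical; keep the stochastic noise term of F5 (default TRUE).
#' @return an object of class `benchmark_function`: a list with elements
#'   `name`, `fname`, `dimension`, `lower`, `upper`, `known_optimum`, `fn`.
#' @examples
#' f <- benchmark_function("F12")
#' f$fn(c(0.0898, -0.7126))
#' @export
benchmark_function <- function(name, dimension = NULL, noisy = TRUE) {
  key <- .bench_resolve(name)
  spec <- .bench_registry[[key]]
  d <- spec$dimension
  if (is.null(d)) {   # scalable function
    d <- if (is.null(dimension)) 30L else as.integer(dimension)
    stopifnot(d >= 1L)
  }
  lower <- rep_len(spec$lower, d)
  upper <- rep_len(spec$upper, d)
  fn <- spec$fn
  if (key == "F5" && !noisy) {
    base <- spec$fn_nonoise
    fn <- base
  }
  structure(
    list(name = key, fname = spec$fname, dimension = d,
         lower = lower, upper = upper,
         known_optimum = spec$optimum, fn = fn),
    class = "benchmark_function"
  )
}

#' @export
print.benchmark_function <- function(x, ...) {
  cat(sprintf("<benchmark_function> %s (%s), d = %d, bounds [%g, %g] x ..., optimum %g\n",
              x$name, x$fname, x$dimension, x$lower[1], x$upper[1],
              x$known_optimum))
  invisible(x)
}

#' Names of the registered benchmark functions
#' @return character vector `"F1".."F13"`.
#' @export
benchmark_names <- function() names(.bench_registry)

#' Metadata table for the benchmark registry
#'
#' @param dimension dimension used for the scalable functions (default 30).
#' @return data.frame with one row per function: name, canonical name,
#'   dimension, bounds and known optimum.
#' @export
benchmark_metadata <- function(dimension = 30L) {
  rows <- lapply(benchmark_names(), function(k) {
    f <- benchmark_function(k, dimension = dimension)
    data.frame(name = f$name, fname = f$fname, dimension = f$dimension,
               lower = f$lower[1], upper = f$upper[1],
               optimum = f$known_optimum, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a benchmark function on each row of a matrix
#'
#' @param fn a `benchmark_function`.
#' @param X numeric matrix with `fn$dimension` columns, one point per row.
#' @return numeric vector of length `nrow(X)`.
#' @export
evaluate_batch <- function(fn, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(numeric(0))
  if (ncol(X) != fn$dimension) {
    stop(sprintf("expected %d columns, got %d", fn$dimension, ncol(X)))
  }
  eval_rows(fn$fn, X)
}

.bench_alias <- c(
  sphere = "F1", schwefel222 = "F2", schwefel12 = "F3", schwefel221 = "F4",
  quartic = "F5", rastrigin = "F6", ackley = "F7", griewank = "F8",
  penalized1 = "F9", penalized2 = "F10", kowalik = "F11",
  sixhump = "F12", branin = "F13"
)

.bench_resolve <- function(name) {
  nm <- tolower(as.character(name))
  keys <- tolower(names(.bench_registry))
  if (nm %in% keys) return(names(.bench_registry)[match(nm, keys)])
  if (nm %in% names(.bench_alias)) return(unname(.bench_alias[nm]))
  stop(sprintf("unknown benchmark function '%s'; valid: %s and aliases %s",
               name, paste(names(.bench_registry), collapse = ", "),
               paste(names(.bench_alias), collapse = ", ")))
}

# u(x, a, k, m) boundary penalty of the Penalized functions.
.bench_penalty <- function(x, a, k, m) {
  out <- numeric(length(x))
  hi <- x > a
  lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  sum(out)
}

.kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
                0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
.kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

.bench_registry <- list(
  F1 = list(fname = "Sphere", lower = -100, upper = 100, optimum = 0,
            fn = function(x) sum(x^2)),
  F2 = list(fname = "Schwefel 2.22", lower = -10, upper = 10, optimum = 0,
            fn = function(x) sum(abs(x)) + prod(abs(x))),
  F3 = list(fname = "Schwefel 1.2", lower = -100, upper = 100, optimum = 0,
            fn = function(x) sum(cumsum(x)^2)),
  F4 = list(fname = "Schwefel 2.21", lower = -100, upper = 100, optimum = 0,
            fn = function(x) max(abs(x))),
  F5 = list(fname = "Quartic with noise", lower = -1.28, upper = 1.28,
            optimum = 0,
            fn = function(x) sum(seq_along(x) * x^4) + stats::runif(1),
            fn_nonoise = function(x) sum(seq_along(x) * x^4)),
  F6 = list(fname = "Rastrigin", lower = -5.12, upper = 5.12, optimum = 0,
            fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10)),
  F7 = list(fname = "Ackley", lower = -32, upper = 32, optimum = 0,
            fn = function(x) {
              d <- length(x)
              -20 * exp(-0.2 * sqrt(sum(x^2) / d)) -
                exp(sum(cos(2 * pi * x)) / d) + 20 + exp(1)
            }),
  F8 = list(fname = "Griewank", lower = -600, upper = 600, optimum = 0,
            # evaluation order (sum/4000 - prod) + 1 so that vanishingly
            # small coordinates yield an exact 0 by cancellation
            fn = function(x) {
              sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1
            }),
  F9 = list(fname = "Penalized 1", lower = -50, upper = 50, optimum = 0,
            fn = function(x) {
              d <- length(x)
              y <- 1 + (x + 1) / 4
              core <- 10 * sin(pi * y[1])^2
              if (d > 1) {
                core <- core + sum((y[-d] - 1)^2 *
                                     (1 + 10 * sin(pi * y[-1])^2))
              }
              core <- core + (y[d] - 1)^2
              pi / d * core + .bench_penalty(x, 10, 100, 4)
            }),
  F10 = list(fname = "Penalized 2", lower = -50, upper = 50, optimum = 0,
             fn = function(x) {
               d <- length(x)
               core <- sin(3 * pi * x[1])^2
               if (d > 1) {
                 core <- core + sum((x[-d] - 1)^2 *
                                      (1 + sin(3 * pi * x[-1])^2))
               }
               core <- core + (x[d] - 1)^2 * (1 + sin(2 * pi * x[d])^2)
               0.1 * core + .bench_penalty(x, 5, 100, 4)
             }),
  F11 = list(fname = "Kowalik", lower = -5, upper = 5, optimum = 3.0749e-4,
             dimension = 4L,
             fn = function(x) {
               b <- .kowalik_b
               sum((.kowalik_a -
                      x[1] * (b^2 + b * x[2]) / (b^2 + b * x[3] + x[4]))^2)
             }),
  F12 = list(fname = "Six-hump camel", lower = -5, upper = 5,
             optimum = -1.0316, dimension = 2L,
             fn = function(x) {
               4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 +
                 x[1] * x[2] - 4 * x[2]^2 + 4 * x[2]^4
             }),
  F13 = list(fname = "Branin", lower = c(-5, 0), upper = c(10, 15),
             optimum = 0.397887, dimension = 2L,
             fn = function(x) {
               (x[2] - 5.1 * x[1]^2 / (4 * pi^2) + 5 * x[1] / pi - 6)^2 +
                 10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10
             })
)
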