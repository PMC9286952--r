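#' Run a seeded benchmark matrix
#'
#' Executes `runs` independent seeded runs of every registered algorithm on
#' every requested benchmark function and aggregates Best/Mean/Worst/Std of
#' the final best values, the usual layout of optimizer comparison tables.
#' The seed of run `r` of algorithm `a` on function `f` is derived
#' deterministically from `(master_seed, a, f, r)`, so the full matrix is
#' reproducible from one integer.
#'
#' @param algorithms character vector of registered optimizer names.
#' @param functions character vector of benchmark function names
#'   (`"F1".."F13"` or aliases).
#' @param runs independent runs per cell (default 30).
#' @param pop,iters optimizer budget (defaults 30 and 500).
#' @param master_seed integer master seed.
#' @param dimension dimension for the scalable functions (default 30).
#' @param store_traces keep the per-iteration best-fitness traces
#'   (default FALSE to save memory).
#' @return a list of class `run_report` with `runs` (per-run data.frame:
#'   `fun`, `algorithm`, `run`, `seed`, `best`, `elapsed`), `aggregates`
#'   (Best/Mean/Worst/Std per cell), `traces` (optional), and the config
#'   echo.
#' @export
run_benchmark_matrix <- function(algorithms = c("aoa", "iaoa"),
                                 functions = benchmark_names(),
                                 runs = 30L, pop = 30L, iters = 500L,
                                 master_seed = 1L, dimension = 30L,
                                 store_traces = FALSE) {
  rows <- list()
  traces <- list()
  for (fname in functions) {
    bf <- benchmark_function(fname, dimension = dimension)
    for (algo in algorithms) {
      opt <- get_optimizer(algo)
      for (r in seq_len(runs)) {
        seed <- derive_seed(master_seed, algo, bf$name, r)
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(
          opt(bf, bf$lower, bf$upper, pop, iters, seed),
          error = function(e) e
        )
        elapsed <- proc.time()[["elapsed"]] - t0
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            fun = bf$name, algorithm = algo, run = r, seed = seed,
            best = NA_real_, elapsed = elapsed,
            error = conditionMessage(res), stringsAsFactors = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          fun = bf$name, algorithm = algo, run = r, seed = seed,
          best = res$best_value, elapsed = elapsed, error = NA_character_,
          stringsAsFactors = FALSE)
        if (store_traces) {
          traces[[paste(bf$name, algo, r, sep = ".")]] <- res$trace
        }
      }
    }
  }
  runs_df <- do.call(rbind, rows)
  agg <- stats::aggregate(best ~ fun + algorithm, data = runs_df,
                          FUN = function(v) c(Best = min(v),
                                              Mean = mean(v),
                                              Worst = max(v),
                                              Std = stats::sd(v)))
  aggregates <- cbind(agg[c("fun", "algorithm")], as.data.frame(agg$best))
  structure(list(runs = runs_df, aggregates = aggregates,
                 traces = if (store_traces) traces else NULL,
                 config = list(algorithms = algorithms,
                               functions = functions, runs = runs,
                               pop = pop, iters = iters,
                               master_seed = master_seed,
                               dimension = dimension)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(format_table(x, style = "tab5"), sep = "\n")
  invisible(x)
}

#' Three-significant-digit scientific notation
#'
#' Formats numbers in the `X.XXE+YY` style used by optimizer comparison
#' tables.
#'
#' @param x numeric vector.
#' @return character vector.
#' @export
format_scientific <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.2E", v)
  }, character(1))
}

#' Format a benchmark report
#'
#' @param report a `run_report`.
#' @param style `"tab5"` (fixed-width text, scientific notation), `"csv"`,
#'   or `"json"`.
#' @return a character vector of lines (`tab5`, `csv`) or a JSON string.
#' @export
format_table <- function(report, style = c("tab5", "csv", "json")) {
  style <- match.arg(style)
  agg <- report$aggregates
  if (style == "json") {
    return(jsonlite::toJSON(list(config = report$config,
                                 aggregates = agg, runs = report$runs),
                            auto_unbox = TRUE, digits = NA, na = "null"))
  }
  if (style == "csv") {
    out <- utils::capture.output(
      utils::write.csv(cbind(agg[c("fun", "algorithm")],
                             Best = format_scientific(agg$Best),
                             Mean = format_scientific(agg$Mean),
                             Worst = format_scientific(agg$Worst),
                             Std = format_scientific(agg$Std)),
                       row.names = FALSE))
    return(out)
  }
  header <- sprintf("%-6s %-10s %-12s %-12s %-12s %-12s",
                    "Fun", "Algorithm", "Best", "Mean", "Worst", "Std")
  lines <- vapply(seq_len(nrow(agg)), function(i) {
    sprintf("%-6s %-10s %-12s %-12s %-12s %-12s",
            agg$fun[i], agg$algorithm[i],
            format_scientific(agg$Best[i]), format_scientific(agg$Mean[i]),
            format_scientific(agg$Worst[i]), format_scientific(agg$Std[i]))
  }, character(1))
  c(header, lines)
}

#' Write a benchmark report to disk
#'
#' Emits `<stem>.json` (full per-run results and config echo) and
#' `<stem>.csv` (formatted aggregates).
#'
#' @param report a `run_report`.
#' @param stem output path without extension.
#' @return the two paths, invisibly.
#' @export
write_report <- function(report, stem) {
  json_path <- paste0(stem, ".json")
  csv_path <- paste0(stem, ".csv")
  writeLines(format_table(report, "json"), json_path)
  writeLines(format_table(report, "csv"), csv_path)
  invisible(c(json_path, csv_path))
}

#' Multistart local-optimization oracle
#'
#' Deterministic verification of a benchmark function's global minimum:
#' Nelder-Mead from `starts` seeded uniform starting points inside the
#' bounds, each polished by a restart from its own solution; returns the
#' best result found.
#'
#' @param fn a `benchmark_function` (use `noisy = FALSE` variants for
#'   stochastic objectives).
#' @param starts number of starting points (default 100).
#' @param seed integer seed for the start draws.
#' @return list with `best_par` and `best_value`.
#' @export
multistart_minimum <- function(fn, starts = 100L, seed = 1L) {
  set.seed(seed)
  d <- fn$dimension
  best <- list(best_par = NULL, best_value = Inf)
  for (s in seq_len(starts)) {
    x0 <- fn$lower + stats::runif(d) * (fn$upper - fn$lower)
    res <- stats::optim(x0, function(x) {
      if (any(x < fn$lower) || any(x > fn$upper)) return(1e10)
      fn$fn(x)
    }, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-14))
    res <- stats::optim(res$par, function(x) {
      if (any(x < fn$lower) || any(x > fn$upper)) return(1e10)
      fn$fn(x)
    }, method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-14))
    if (res$value < best$best_value) {
      best <- list(best_par = res$par, best_value = res$value)
    }
  }
  best
}
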