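#' Hyperparameter search space for the DBN
#'
#' Candidates are 2-dimensional continuous vectors: the first coordinate is
#' the natural-log learning rate (searched on a log scale), the second the
#' batch size, decoded by nearest-integer rounding. Decoding always clips
#' into the stated ranges.
#'
#' @param alpha_range learning-rate range (default `c(0.001, 0.5)`).
#' @param beta_range integer batch-size range (default `c(4, 64)`).
#' @return a list of class `search_space` with `lower`/`upper` encoding
#'   bounds for the optimizer.
#' @export
search_space <- function(alpha_range = c(0.001, 0.5),
                         beta_range = c(4L, 64L)) {
  stopifnot(length(alpha_range) == 2, all(alpha_range > 0),
            alpha_range[1] <= alpha_range[2],
            length(beta_range) == 2, beta_range[1] <= beta_range[2],
            beta_range[1] >= 1)
  structure(list(alpha_range = as.numeric(alpha_range),
                 beta_range = as.integer(beta_range),
                 lower = c(log(alpha_range[1]), beta_range[1]),
                 upper = c(log(alpha_range[2]), beta_range[2])),
            class = "search_space")
}

#' Decode a candidate vector into (alpha, beta)
#'
#' @param z length-2 numeric vector on the encoding scale.
#' @param space a [search_space()].
#' @return list with `alpha` (numeric) and `beta` (integer), both in range.
#' @export
decode_candidate <- function(z, space) {
  alpha <- exp(min(max(z[1], space$lower[1]), space$upper[1]))
  alpha <- min(max(alpha, space$alpha_range[1]), space$alpha_range[2])
  beta <- as.integer(round(min(max(z[2], space$lower[2]), space$upper[2])))
  beta <- min(max(beta, space$beta_range[1]), space$beta_range[2])
  list(alpha = alpha, beta = beta)
}

#' Fitness of a DBN hyperparameter candidate
#'
#' Trains a DBN with the decoded learning rate and batch size on the
#' training split and returns `1 - error rate` on the inner validation
#' split. Training randomness is derived deterministically from the
#' candidate and `fit_seed`, so the fitness is a deterministic function of
#' the candidate and the optimizer's own RNG stream is left untouched.
#'
#' @param z length-2 candidate on the encoding scale.
#' @param train,val `feature_table`s for training and inner validation.
#' @param space a [search_space()].
#' @param config base [dbn_config()] whose `alpha`/`batch_size` are
#'   overridden.
#' @param fit_seed integer seed mixed with the candidate.
#' @return validation accuracy in `[0, 1]`.
#' @export
dbn_fitness <- function(z, train, val, space = search_space(),
                        config = dbn_config(), fit_seed = 1L) {
  dec <- decode_candidate(z, space)
  cfg <- config
  cfg$alpha <- dec$alpha
  cfg$batch_size <- min(dec$beta, nrow(train$values))
  cfg$seed <- NULL
  seed <- derive_seed(fit_seed, "fitness",
                      sprintf("%.8f", dec$alpha), dec$beta)
  model <- with_preserved_rng(seed, {
    dbn_train(train$values, train$labels, cfg)
  })
  pred <- predict(model, val$values)
  mean(pred == val$labels)
}

# -- optimizer plugin registry -------------------------------------------

.optimizer_registry <- new.env(parent = emptyenv())

#' Register an optimizer plugin
#'
#' An optimizer is a function `f(objective, lower, upper, pop, iters, seed)`
#' returning a list with at least `best_par` and `best_value`
#' (minimization). The built-in `"aoa"` and `"iaoa"` entries are registered
#' at load time; third-party metaheuristics can be added for side-by-side
#' benchmarking.
#'
#' @param name identifier.
#' @param fn the optimizer function.
#' @export
register_optimizer <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .optimizer_registry)
  invisible(name)
}

#' @rdname register_optimizer
#' @export
registered_optimizers <- function() sort(ls(.optimizer_registry))

#' @rdname register_optimizer
#' @return `get_optimizer` returns the registered function.
#' @export
get_optimizer <- function(name) {
  if (!exists(name, envir = .optimizer_registry, inherits = FALSE)) {
    stop(sprintf("unknown optimizer '%s'; registered: %s", name,
                 paste(registered_optimizers(), collapse = ", ")))
  }
  get(name, envir = .optimizer_registry, inherits = FALSE)
}

.register_builtin_optimizers <- function() {
  register_optimizer("aoa", function(objective, lower, upper, pop, iters,
                                     seed) {
    aoa_optimize(objective, lower, upper,
                 aoa_config(pop = pop, iters = iters, seed = seed))
  })
  register_optimizer("iaoa", function(objective, lower, upper, pop, iters,
                                      seed) {
    iaoa_optimize(objective, lower, upper,
                  iaoa_config(pop = pop, iters = iters, seed = seed))
  })
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_optimizers()
}

#' Metaheuristic tuning of the DBN learning rate and batch size
#'
#' Outer stratified k-fold cross-validation: each fold is held out as a test
#' set; the remainder is split into a training portion and a stratified
#' inner-validation portion; the optimizer searches (alpha, beta) to
#' maximize inner-validation accuracy (the objective handed to the
#' minimizer is the error rate); the DBN is then retrained on the full
#' remainder with the tuned pair and scored on the held-out fold. The outer
#' test fold never enters a fitness evaluation.
#'
#' @param table a [feature_table()].
#' @param space a [search_space()].
#' @param optimizer name of a registered optimizer (`"iaoa"`, `"aoa"`, ...)
#'   or an optimizer function (see [register_optimizer()]).
#' @param pop,iters optimizer budget per fold (defaults 20 and 30).
#' @param folds outer folds (default 10).
#' @param seed master seed; every fold, split and fit derives its own
#'   stream from it.
#' @param config base [dbn_config()] used for the final per-fold retrain.
#' @param search_config optional cheaper [dbn_config()] used inside the
#'   fitness evaluations (defaults to `config`).
#' @param inner_val_fraction fraction of the training portion held out for
#'   inner validation (default 0.2).
#' @return list of class `dbn_tuning`: `per_fold` data.frame
#'   (fold, alpha, beta, test_accuracy), `mean_accuracy`, and the call
#'   configuration.
#' @export
tune_dbn <- function(table, space = search_space(), optimizer = "iaoa",
                     pop = 20L, iters = 30L, folds = 10L, seed = 1L,
                     config = dbn_config(), search_config = NULL,
                     inner_val_fraction = 0.2) {
  opt_fn <- if (is.function(optimizer)) optimizer else get_optimizer(optimizer)
  opt_name <- if (is.function(optimizer)) "custom" else optimizer
  if (is.null(search_config)) search_config <- config
  fold_id <- stratified_folds(table$labels, folds,
                              seed = derive_seed(seed, "outer-folds"))
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    rest_idx <- which(!te)
    y_rest <- table$labels[rest_idx]
    # stratified inner validation split of the remainder
    inner_k <- max(2L, round(1 / inner_val_fraction))
    inner_id <- stratified_folds(y_rest, inner_k,
                                 seed = derive_seed(seed, "inner", f))
    val_idx <- rest_idx[inner_id == 1L]
    tr_idx <- rest_idx[inner_id != 1L]
    tr <- feature_table(table$values[tr_idx, , drop = FALSE],
                        table$labels[tr_idx], kinds = table$kinds)
    va <- feature_table(table$values[val_idx, , drop = FALSE],
                        table$labels[val_idx], kinds = table$kinds)
    fit_seed <- derive_seed(seed, "fit", f)
    objective <- function(z) {
      1 - dbn_fitness(z, tr, va, space, search_config, fit_seed = fit_seed)
    }
    res <- opt_fn(objective, space$lower, space$upper, pop, iters,
                  derive_seed(seed, "opt", opt_name, f))
    dec <- decode_candidate(res$best_par, space)
    cfg <- config
    cfg$alpha <- dec$alpha
    cfg$batch_size <- min(dec$beta, length(rest_idx))
    cfg$seed <- derive_seed(seed, "retrain", f)
    model <- dbn_train(table$values[rest_idx, , drop = FALSE], y_rest, cfg)
    pred <- predict(model, table$values[te, , drop = FALSE])
    rows[[f]] <- data.frame(fold = f, alpha = dec$alpha, beta = dec$beta,
                            test_accuracy = mean(pred == table$labels[te]))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$test_accuracy),
                 optimizer = opt_name, pop = pop, iters = iters,
                 folds = folds, seed = seed),
            class = "dbn_tuning")
}

#' @export
print.dbn_tuning <- function(x, ...) {
  cat(sprintf("<dbn_tuning> %s, %d folds: mean accuracy %.4f\n",
              x$optimizer, x$folds, x$mean_accuracy))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
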