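#' Clip a position matrix to box bounds
#'
#' Component-wise clipping of an `n x d` matrix of candidate positions to
#' per-dimension `[lower, upper]` bounds.
#'
#' @param X numeric matrix, one candidate per row.
#' @param lower,upper numeric vectors of length `ncol(X)` (scalars are
#'   recycled).
#' @return matrix of the same shape with every entry inside the bounds.
#' @export
clip_bounds <- function(X, lower, upper) {
  X <- as.matrix(X)
  d <- ncol(X)
  lower <- rep_len(lower, d)
  upper <- rep_len(upper, d)
  lo <- matrix(lower, nrow(X), d, byrow = TRUE)
  hi <- matrix(upper, nrow(X), d, byrow = TRUE)
  pmin(pmax(X, lo), hi)
}

#' Derive a reproducible child seed from a master seed and labels
#'
#' Stable polynomial hash of a master seed plus an arbitrary sequence of
#' string/integer tokens, reduced modulo 2^31 - 1 so the result is always a
#' valid 32-bit seed. Used to give every (algorithm, function, run) cell of a
#' benchmark matrix, every cross-validation fold, etc. its own deterministic
#' RNG stream from one integer.
#'
#' @param master integer master seed.
#' @param ... further tokens (coerced to character) mixed into the hash.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  tokens <- unlist(lapply(list(...), as.character))
  h <- as.numeric(master) %% 2147483647
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` cross-validation folds so that class
#' proportions are preserved up to one sample per class.
#'
#' @param y binary label vector (0/1).
#' @param k number of folds.
#' @param seed optional integer seed for the shuffle.
#' @return integer vector of fold ids in `1..k`, same length as `y`.
#' @export
stratified_folds <- function(y, k = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (min(tabulate(folds, k)) == 0) {
    stop("a fold received no samples; reduce k or supply more data")
  }
  folds
}

# Logistic sigmoid; the plain form saturates cleanly to 0/1 in double
# precision at the extremes.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Add a per-column bias vector to a matrix (fast replacement for sweep).
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Evaluate an objective on each row of X.
eval_rows <- function(objective, X) {
  n <- nrow(X)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(i) objective(X[i, ]), numeric(1))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards (used to make stochastic fitness functions a
# deterministic function of the candidate).
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}
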