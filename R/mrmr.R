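#' Equal-frequency discretization
#'
#' Bins a continuous column at its empirical quantiles. Duplicate quantiles
#' (heavy ties) collapse, so the realized number of bins can be smaller
#' than requested. Discrete columns should be passed through unchanged.
#'
#' @param x numeric vector.
#' @param bins requested number of bins (default 10).
#' @return integer vector of bin codes.
#' @export
discretize_equal_frequency <- function(x, bins = 10L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) < 2) return(rep.int(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

# Map a column to discrete codes according to its kind.
mi_codes <- function(x, kind = "continuous", bins = 10L) {
  if (kind == "discrete") return(match(x, sort(unique(x))))
  discretize_equal_frequency(x, bins)
}

#' Mutual information between two columns (bits)
#'
#' Plug-in estimate from the joint contingency table of the (discretized)
#' columns: `I(x;y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`. Continuous
#' columns are discretized into equal-frequency bins first. The estimate is
#' symmetric and non-negative; a constant column has zero entropy and
#' yields 0.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param bins bins for continuous columns (default 10).
#' @param kinds character vector of length 2 giving the kind
#'   (`"discrete"`/`"continuous"`) of `x` and `y`; by default both are
#'   auto-detected with a 10-level threshold.
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 10L, kinds = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (is.null(kinds)) {
    kinds <- c(if (length(unique(x)) <= 10) "discrete" else "continuous",
               if (length(unique(y)) <= 10) "discrete" else "continuous")
  }
  cx <- mi_codes(x, kinds[1], bins)
  cy <- mi_codes(y, kinds[2], bins)
  mi_from_codes(cx, cy)
}

# Contingency-table MI in bits from integer codes.
mi_from_codes <- function(cx, cy) {
  joint <- table(cx, cy) / length(cx)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

# Discretize a whole feature table once; returns list of code vectors plus
# label codes.
table_codes <- function(table, bins = 10L) {
  codes <- lapply(seq_len(ncol(table$values)), function(j) {
    mi_codes(table$values[, j], table$kinds[j], bins)
  })
  list(features = codes, labels = table$labels + 1L)
}

#' Relevance of a feature subset
#'
#' Mean mutual information between each feature in the subset and the class
#' label.
#'
#' @param table a [feature_table()].
#' @param subset integer or character vector of features (non-empty).
#' @param bins bins for continuous columns.
#' @return mean feature-label MI in bits.
#' @export
relevance <- function(table, subset, bins = 10L) {
  idx <- resolve_subset(table, subset)
  codes <- table_codes(table, bins)
  mean(vapply(idx, function(j) {
    mi_from_codes(codes$features[[j]], codes$labels)
  }, numeric(1)))
}

#' Redundancy of a feature subset
#'
#' `(1/|S|^2) * sum I(x_i; x_j)` over all ordered pairs of the subset,
#' self-pairs included by default (each feature's entropy enters the
#' double sum once).
#'
#' @inheritParams relevance
#' @param include_self include the `i == j` self-pairs (default TRUE).
#' @return redundancy in bits.
#' @export
redundancy <- function(table, subset, bins = 10L, include_self = TRUE) {
  idx <- resolve_subset(table, subset)
  codes <- table_codes(table, bins)
  redundancy_from_codes(codes$features, idx, include_self)
}

redundancy_from_codes <- function(codes, idx, include_self = TRUE) {
  k <- length(idx)
  tot <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (!include_self && a == b) next
      if (b < a) next
      m <- mi_from_codes(codes[[idx[a]]], codes[[idx[b]]])
      tot <- tot + if (a == b) m else 2 * m   # symmetric: count (a,b),(b,a)
    }
  }
  tot / k^2
}

resolve_subset <- function(table, subset) {
  if (length(subset) == 0) stop("feature subset must be non-empty")
  if (is.character(subset)) {
    idx <- match(subset, table$feature_names)
    if (anyNA(idx)) stop("unknown feature name(s)")
    idx
  } else {
    as.integer(subset)
  }
}

#' MRMR greedy feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance selection. Step 1 picks the
#' feature with the largest mutual information with the label; step 2 adds
#' the feature least redundant with the selected set; each later step adds
#' the feature maximizing `Phi = D - R` of the augmented set, where `D` is
#' the mean feature-label MI and `R` the mean pairwise feature MI. Ties
#' break toward the lower column index.
#'
#' @param table a [feature_table()].
#' @param k number of features to rank (default all).
#' @param bins bins for continuous columns (default 10).
#' @param step2 `"paper"` uses pure minimum redundancy at step 2;
#'   `"mid"` uses the `Phi` criterion from step 2 onward.
#' @param include_self include self-pairs in the redundancy denominator.
#' @return an object of class `mrmr_ranking`: data.frame with columns
#'   `rank`, `feature`, `index`, `relevance`, `redundancy`, `score`
#'   (`score = relevance - redundancy` of the selected set at that step).
#' @export
mrmr_rank <- function(table, k = NULL, bins = 10L,
                      step2 = c("paper", "mid"), include_self = TRUE) {
  step2 <- match.arg(step2)
  p <- ncol(table$values)
  if (is.null(k)) k <- p
  if (k > p) stop(sprintf("k = %d exceeds the %d available features", k, p))
  out <- data.frame(rank = integer(0), feature = character(0),
                    index = integer(0), relevance = numeric(0),
                    redundancy = numeric(0), score = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("mrmr_ranking", "data.frame")
  if (k == 0L) return(out)
  codes <- table_codes(table, bins)
  rel <- vapply(seq_len(p), function(j) {
    mi_from_codes(codes$features[[j]], codes$labels)
  }, numeric(1))
  selected <- integer(0)
  rows <- vector("list", k)
  for (step in seq_len(k)) {
    remaining <- setdiff(seq_len(p), selected)
    if (step == 1L) {
      pick <- remaining[which.max(rel[remaining])]
    } else if (step == 2L && step2 == "paper") {
      red2 <- vapply(remaining, function(j) {
        redundancy_from_codes(codes$features, c(selected, j), include_self)
      }, numeric(1))
      pick <- remaining[which.min(red2)]
    } else {
      phi <- vapply(remaining, function(j) {
        s <- c(selected, j)
        mean(rel[s]) - redundancy_from_codes(codes$features, s, include_self)
      }, numeric(1))
      pick <- remaining[which.max(phi)]
    }
    selected <- c(selected, pick)
    D <- mean(rel[selected])
    R <- redundancy_from_codes(codes$features, selected, include_self)
    rows[[step]] <- data.frame(rank = step,
                               feature = table$feature_names[pick],
                               index = pick, relevance = D, redundancy = R,
                               score = D - R, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mrmr_ranking", "data.frame")
  out
}

#' Incremental-subset accuracy curve
#'
#' For `k = 1..p`, estimates the stratified 10-fold cross-validation
#' accuracy of a small single-hidden-layer feedforward classifier trained on
#' the top-`k` ranked features, and reports the smallest `k` attaining the
#' maximum of the curve as the optimal subset size.
#'
#' @param table a [feature_table()].
#' @param ranking an `mrmr_ranking` covering all features of `table`.
#' @param folds number of CV folds (default 10).
#' @param hidden hidden-layer width of the verification network (default 16).
#' @param maxit training iterations per fit (default 150).
#' @param decay weight decay of the verification network (default 0.01).
#' @param seed integer seed controlling fold assignment and weight init.
#' @return list with `accuracy` (length-`p` curve), `optimal_k`, and
#'   `features` (the top-`optimal_k` feature names).
#' @export
incremental_subset_accuracy <- function(table, ranking, folds = 10L,
                                        hidden = 16L, maxit = 150L,
                                        decay = 0.01, seed = 1L) {
  p <- ncol(table$values)
  if (nrow(ranking) != p) stop("ranking must cover all features")
  ord <- ranking$index
  fold_id <- stratified_folds(table$labels, folds,
                              seed = derive_seed(seed, "subset-folds"))
  acc <- numeric(p)
  for (k in seq_len(p)) {
    X <- scale(table$values[, ord[seq_len(k)], drop = FALSE])
    X[is.nan(X)] <- 0   # constant column safeguard
    y <- table$labels
    correct <- 0L
    for (f in seq_len(folds)) {
      te <- fold_id == f
      set.seed(derive_seed(seed, "nnet", k, f))
      fit <- nnet::nnet(X[!te, , drop = FALSE], y[!te], size = hidden,
                        maxit = maxit, decay = decay, trace = FALSE)
      pred <- as.integer(stats::predict(fit, X[te, , drop = FALSE]) > 0.5)
      correct <- correct + sum(pred == y[te])
    }
    acc[k] <- correct / length(y)
  }
  optimal_k <- which.max(acc)   # which.max returns the smallest maximizer
  list(accuracy = acc, optimal_k = optimal_k,
       features = table$feature_names[ord[seq_len(optimal_k)]])
}
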