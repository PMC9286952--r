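# Independent oracles used across the suite. These are deliberately naive
# (full enumeration, explicit loops) and share no code with the package
# internals they check.

# All 2^k binary state vectors as rows.
enumerate_states <- function(k) {
  m <- as.matrix(expand.grid(rep(list(0:1), k)))
  dimnames(m) <- NULL
  m
}

# Exact E(v, h) computed with explicit loops.
oracle_energy <- function(W, a, b, v, h) {
  e <- 0
  for (i in seq_along(v)) {
    for (j in seq_along(h)) e <- e - W[i, j] * v[i] * h[j]
  }
  e - sum(a * v) - sum(b * h)
}

# Exact P(h_j = 1 | v) by summing Boltzmann weights over all hidden states.
oracle_hidden_conditional <- function(W, a, b, v) {
  H <- enumerate_states(ncol(W))
  wts <- apply(H, 1, function(h) exp(-oracle_energy(W, a, b, v, h)))
  colSums(H * wts) / sum(wts)
}

# Exact P(v_i = 1 | h) by symmetry.
oracle_visible_conditional <- function(W, a, b, h) {
  V <- enumerate_states(nrow(W))
  wts <- apply(V, 1, function(v) exp(-oracle_energy(W, a, b, v, h)))
  colSums(V * wts) / sum(wts)
}

# Exact p(v) of a tiny RBM via the full partition function.
oracle_visible_marginal <- function(W, a, b, v) {
  H <- enumerate_states(ncol(W))
  V <- enumerate_states(nrow(W))
  num <- sum(apply(H, 1, function(h) exp(-oracle_energy(W, a, b, v, h))))
  Z <- sum(apply(V, 1, function(vv) {
    sum(apply(H, 1, function(h) exp(-oracle_energy(W, a, b, vv, h))))
  }))
  num / Z
}

# Plug-in mutual information (bits) via explicit loops over observed
# level pairs.
oracle_mi <- function(cx, cy) {
  n <- length(cx)
  out <- 0
  for (ux in unique(cx)) {
    for (uy in unique(cy)) {
      pxy <- sum(cx == ux & cy == uy) / n
      if (pxy == 0) next
      px <- sum(cx == ux) / n
      py <- sum(cy == uy) / n
      out <- out + pxy * log2(pxy / (px * py))
    }
  }
  out
}

# Exhaustive MRMR sequence following the three-step rule: argmax relevance,
# then pure minimum redundancy, then exhaustive Phi maximization of the
# augmented set; ties to the lower index.
oracle_mrmr_sequence <- function(codes, label_codes, k,
                                 include_self = TRUE) {
  p <- length(codes)
  red <- function(idx) {
    tot <- 0
    for (a in idx) for (b in idx) {
      if (!include_self && a == b) next
      tot <- tot + oracle_mi(codes[[a]], codes[[b]])
    }
    tot / length(idx)^2
  }
  rel <- vapply(codes, function(cx) oracle_mi(cx, label_codes), numeric(1))
  sel <- which.max(rel)
  while (length(sel) < k) {
    remaining <- setdiff(seq_len(p), sel)
    score <- if (length(sel) == 1L) {
      -vapply(remaining, function(j) red(c(sel, j)), numeric(1))
    } else {
      vapply(remaining, function(j) {
        s <- c(sel, j)
        mean(rel[s]) - red(s)
      }, numeric(1))
    }
    sel <- c(sel, remaining[which.max(score)])
  }
  sel
}

# Small discrete feature table with a planted structure: f1 = label copy,
# f2 = copy of f1, f3 = independent noise.
make_copy_table <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  f1 <- y
  f2 <- y
  f3 <- sample(0:1, n, replace = TRUE)
  feature_table(cbind(f1 = f1, f2 = f2, f3 = f3), y)
}
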