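# Independent brute-force oracles for the stability measures and the Pareto
# front. Deliberately written as direct, naive translations of the defining
# formulas (explicit set operations, double loops) sharing no code with the
# package internals.

oracle_pairs <- function(sets, pairfun) {
  m <- length(sets)
  vals <- c()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      vals <- c(vals, pairfun(sets[[i]], sets[[j]]))
    }
  }
  mean(vals)
}

oracle_jaccard <- function(sets, p) {
  oracle_pairs(sets, function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
  })
}

oracle_dice <- function(sets, p) {
  oracle_pairs(sets, function(a, b) {
    2 * length(intersect(a, b)) / (length(a) + length(b))
  })
}

oracle_ochiai <- function(sets, p) {
  oracle_pairs(sets, function(a, b) {
    length(intersect(a, b)) / sqrt(length(a) * length(b))
  })
}

oracle_lustgarten <- function(sets, p) {
  oracle_pairs(sets, function(a, b) {
    (length(intersect(a, b)) - length(a) * length(b) / p) /
      (min(length(a), length(b)) - max(0, length(a) + length(b) - p))
  })
}

oracle_zucknick <- function(sets, p, cormat) {
  oracle_pairs(sets, function(a, b) {
    u <- union(a, b)
    cors <- c()
    if (length(u) >= 2) {
      for (ii in seq_along(u)) {
        for (jj in seq_along(u)) {
          if (ii < jj) cors <- c(cors, cormat[u[ii], u[jj]])
        }
      }
    }
    r <- if (length(cors)) median(cors) else Inf
    cab <- 0
    for (xx in a) {
      for (yy in setdiff(b, a)) {
        if (cormat[xx, yy] > r) cab <- cab + cormat[xx, yy]
      }
    }
    cab <- cab / length(b)
    dab <- 0
    for (xx in b) {
      for (yy in setdiff(a, b)) {
        if (cormat[xx, yy] > r) dab <- dab + cormat[xx, yy]
      }
    }
    dab <- dab / length(a)
    (length(intersect(a, b)) + cab + dab) / length(union(a, b))
  })
}

oracle_novovicova <- function(sets, p) {
  m <- length(sets)
  h <- sapply(seq_len(p), function(j) sum(sapply(sets, function(s) j %in% s)))
  q <- sum(h)
  tot <- 0
  for (j in seq_len(p)) {
    if (h[j] > 0) tot <- tot + h[j] * log2(h[j])
  }
  tot / (q * log2(m))
}

oracle_davis <- function(sets, p, alpha) {
  m <- length(sets)
  h <- sapply(seq_len(p), function(j) sum(sapply(sets, function(s) j %in% s)))
  nv <- length(unique(unlist(sets)))
  max(0, sum(h / m) / nv - alpha * median(sapply(sets, length)) / p)
}

oracle_somol <- function(sets, p) {
  m <- length(sets)
  h <- sapply(seq_len(p), function(j) sum(sapply(sets, function(s) j %in% s)))
  q <- sum(h)
  d <- sum(sapply(seq_len(p), function(j) {
    if (h[j] == 0) 0 else (h[j] / q) * (h[j] - 1) / (m - 1)
  }))
  cmin <- (q^2 - p * (q - q %% p) - (q %% p)^2) / (p * q * (m - 1))
  cmax <- ((q %% m)^2 + q * (m - 1) - (q %% m) * m) / (q * (m - 1))
  (d - cmin) / (cmax - cmin)
}

oracle_correlation <- function(sets, p) {
  ind <- function(s) as.numeric(seq_len(p) %in% s)
  oracle_pairs(sets, function(a, b) stats::cor(ind(a), ind(b)))
}

# random ensemble with varying set sizes in [1, p - 1] (so that every measure
# is defined and oracle comparison is exact)
rand_ens_sets <- function(m, p) {
  lapply(seq_len(m), function(i) sort(sample.int(p, sample.int(p - 1, 1))))
}

# Pareto-front oracle: full pairwise dominance matrices built with outer(),
# structurally different from the package's per-point scan.
oracle_front_idx <- function(mat) {
  n <- nrow(mat)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(mat))) {
    le <- le & outer(mat[, k], mat[, k], "<=")
    lt <- lt | outer(mat[, k], mat[, k], "<")
  }
  dominated <- apply(le & lt, 2, any)
  which(!dominated)
}
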