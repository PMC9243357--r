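# Independent brute-force oracles used to verify the package's feature
# math and statistics. These deliberately use naive enumeration (nested
# loops, recursion, exhaustive sweeps) rather than the package's
# vectorized code paths.

# rank AUC by exhaustive pairwise concordance, ties counted 1/2
oracle_auc <- function(x, labels) {
  pos <- x[labels == 1]
  neg <- x[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# co-occurrence counts for one direction by voxel-by-voxel enumeration
oracle_glcm_counts <- function(levels, d, n_levels) {
  dm <- dim(levels)
  M <- matrix(0, n_levels, n_levels)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    a <- levels[i, j, k]
    if (is.na(a)) next
    ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
    if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
    b <- levels[ii, jj, kk]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# run enumeration along one direction: walk each run start to its end
oracle_runs <- function(levels, d) {
  dm <- dim(levels)
  inb <- function(p) all(p >= 1) && all(p <= dm)
  runs <- NULL
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    p <- c(i, j, k)
    v <- levels[i, j, k]
    if (is.na(v)) next
    prev <- p - d
    if (inb(prev) && !is.na(levels[prev[1], prev[2], prev[3]]) &&
        levels[prev[1], prev[2], prev[3]] == v) next  # not a run start
    len <- 1
    q <- p + d
    while (inb(q) && !is.na(levels[q[1], q[2], q[3]]) &&
           levels[q[1], q[2], q[3]] == v) {
      len <- len + 1
      q <- q + d
    }
    runs <- rbind(runs, c(v, len))
  }
  runs
}

# 26-connected zones of equal level via depth-first flood fill
oracle_zones <- function(levels) {
  dm <- dim(levels)
  seen <- array(FALSE, dm)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  zones <- NULL
  for (start in which(!is.na(levels))) {
    if (seen[start]) next
    lv <- levels[start]
    stack <- list(arrayInd(start, dm)[1, ])
    seen[start] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > dm)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- levels[q[1], q[2], q[3]]
        if (is.na(v) || v != lv) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    zones <- rbind(zones, c(lv, size))
  }
  zones
}

# per-voxel dependence (1 + equal-level 26-neighbors) by enumeration
oracle_dependence <- function(levels) {
  dm <- dim(levels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  out <- NULL
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    v <- levels[i, j, k]
    if (is.na(v)) next
    dep <- 1
    for (r in seq_len(nrow(offs))) {
      q <- c(i, j, k) + offs[r, ]
      if (any(q < 1) || any(q > dm)) next
      w <- levels[q[1], q[2], q[3]]
      if (!is.na(w) && w == v) dep <- dep + 1
    }
    out <- rbind(out, c(v, dep))
  }
  out
}

# neighborhood means for the gray-tone difference statistics
oracle_ngtdm_si <- function(levels, n_levels) {
  dm <- dim(levels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  s_i <- numeric(n_levels)
  n_i <- integer(n_levels)
  nvp <- 0
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    v <- levels[i, j, k]
    if (is.na(v)) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(i, j, k) + offs[r, ]
      if (any(q < 1) || any(q > dm)) next
      w <- levels[q[1], q[2], q[3]]
      if (!is.na(w)) nb <- c(nb, w)
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    n_i[v] <- n_i[v] + 1L
    s_i[v] <- s_i[v] + abs(v - mean(nb))
  }
  list(s_i = s_i, n_i = n_i, nvp = nvp)
}

# greedy redundancy-removal simulator (independent of the package's code)
oracle_redundancy <- function(X, labels, threshold = 0.90) {
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    rho <- abs(stats::cor(X[, keep, drop = FALSE], method = "spearman"))
    diag(rho) <- 0
    if (max(rho) < threshold) break
    # strongest pair; ties by lexicographic name order
    cand <- NULL
    for (a in keep) for (b in keep) {
      if (a < b && rho[a, b] == max(rho)) cand <- rbind(cand, c(a, b))
    }
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    best <- list(a = cand[1, 1], b = cand[1, 2])
    auc_a <- oracle_auc(X[, best$a], labels)
    auc_a <- max(auc_a, 1 - auc_a)
    auc_b <- oracle_auc(X[, best$b], labels)
    auc_b <- max(auc_b, 1 - auc_b)
    drop <- if (auc_a < auc_b) best$a else if (auc_b < auc_a) best$b else
      max(best$a, best$b)
    keep <- setdiff(keep, drop)
  }
  colnames(X)[colnames(X) %in% keep]
}

# small helper: constant-intensity cuboid lesion in a larger grid
toy_volume <- function(values, dims = dim(values)) {
  ct_volume(array(values, dims), spacing = c(1, 1, 1))
}
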