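# Independent brute-force oracles. These deliberately share no code with the
# package: plain triple loops and exhaustive enumeration, usable only on tiny
# inputs.

oracle_offsets <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# enumerate GLCM/GLRLM/GLSZM/NGTDM counts by walking every voxel
oracle_counts <- function(lev, n_levels) {
  d <- dim(lev)
  inside <- function(v) all(v >= 1) && all(v <= d)
  at <- function(v) lev[v[1], v[2], v[3]]

  glcm <- matrix(0, n_levels, n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l1 <- lev[x, y, z]
    if (l1 == 0) next
    for (k in 1:nrow(oracle_offsets)) {
      v <- c(x, y, z) + oracle_offsets[k, ]
      if (!inside(v)) next
      l2 <- at(v)
      if (l2 == 0) next
      glcm[l1, l2] <- glcm[l1, l2] + 1
      glcm[l2, l1] <- glcm[l2, l1] + 1
    }
  }

  runs <- list()
  for (k in 1:nrow(oracle_offsets)) {
    dir <- oracle_offsets[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      v <- c(x, y, z)
      l <- at(v)
      if (l == 0) next
      prev <- v - dir
      if (inside(prev) && at(prev) == l) next  # not a run start
      len <- 1
      nxt <- v + dir
      while (inside(nxt) && at(nxt) == l) {
        len <- len + 1
        nxt <- nxt + dir
      }
      runs[[length(runs) + 1]] <- c(l, len)
    }
  }
  runs <- do.call(rbind, runs)
  glrlm <- matrix(0, n_levels, max(runs[, 2]))
  for (i in 1:nrow(runs)) {
    glrlm[runs[i, 1], runs[i, 2]] <- glrlm[runs[i, 1], runs[i, 2]] + 1
  }

  # zones: repeated neighborhood expansion (26-connectivity)
  zone_id <- array(0L, d)
  nz <- 0L
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (lev[x, y, z] == 0 || zone_id[x, y, z] > 0) next
    nz <- nz + 1L
    l <- lev[x, y, z]
    frontier <- list(c(x, y, z))
    zone_id[x, y, z] <- nz
    size <- 1L
    while (length(frontier)) {
      nxt <- list()
      for (v in frontier) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          w <- v + c(dx, dy, dz)
          if (!inside(w)) next
          if (at(w) == l && zone_id[w[1], w[2], w[3]] == 0L) {
            zone_id[w[1], w[2], w[3]] <- nz
            size <- size + 1L
            nxt[[length(nxt) + 1]] <- w
          }
        }
      }
      frontier <- nxt
    }
    zones[[nz]] <- c(l, size)
  }
  zones <- do.call(rbind, zones)
  glszm <- matrix(0, n_levels, max(zones[, 2]))
  for (i in 1:nrow(zones)) {
    glszm[zones[i, 1], zones[i, 2]] <- glszm[zones[i, 1], zones[i, 2]] + 1
  }

  ngtdm_n <- ngtdm_s <- numeric(n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    l <- lev[x, y, z]
    if (l == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- c(x + dx, y + dy, z + dz)
      if (!inside(w)) next
      lw <- at(w)
      if (lw > 0) nb <- c(nb, lw)
    }
    if (length(nb) == 0) next
    ngtdm_n[l] <- ngtdm_n[l] + 1
    ngtdm_s[l] <- ngtdm_s[l] + abs(l - mean(nb))
  }

  list(glcm = glcm, glrlm = glrlm, glszm = glszm,
       ngtdm_n = ngtdm_n, ngtdm_s = ngtdm_s)
}

# Mann-Whitney pair-counting AUC (ties count one half)
oracle_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  wins <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(wins)
}

# exhaustive best k-subset least squares: support minimizing the residual
oracle_best_subset <- function(F, f, k) {
  subsets <- utils::combn(ncol(F), k, simplify = FALSE)
  best <- NULL
  best_r <- Inf
  for (s in subsets) {
    fit <- qr(F[, s, drop = FALSE])
    if (fit$rank < length(s)) next
    r <- sqrt(sum(qr.resid(fit, f)^2))
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- s
    }
  }
  list(support = sort(best), residual = best_r)
}

# exhaustive best feature pair: the 2-subset of columns minimizing the
# least-squares residual of the class indicator
oracle_best_pair <- function(x, y) {
  xs <- scale(x)
  best <- NULL
  best_r <- Inf
  for (i in 1:(ncol(x) - 1)) for (j in (i + 1):ncol(x)) {
    r <- sum(qr.resid(qr(cbind(1, xs[, c(i, j)])), y)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- c(i, j)
    }
  }
  sort(best)
}
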