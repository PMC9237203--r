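# Independent brute-force enumerators for the texture-matrix families,
# used as oracles against the package's builders on small random VOIs.
# They share only the *conventions* (13-direction order, 26-connectivity),
# not code: everything here is computed by direct per-voxel enumeration.

ORACLE_DIRS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

ALL_OFFSETS <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
ALL_OFFSETS <- ALL_OFFSETS[rowSums(abs(ALL_OFFSETS)) > 0, ]

# random VOI as a bounding-box level array with NA holes
random_level_array <- function(max_dim = 5L, ng = 4L, p_na = 0.3) {
  d <- sample(2:max_dim, 3, replace = TRUE)
  arr <- array(sample.int(ng, prod(d), replace = TRUE), dim = d)
  arr[runif(length(arr)) < p_na] <- NA_integer_
  if (all(is.na(arr))) arr[1] <- 1L
  arr
}

dvoi_from_array <- function(arr, ng) {
  sel <- which(!is.na(arr))
  d <- dim(arr)
  i0 <- sel - 1L
  coords <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  structure(list(coords = coords, levels = as.integer(arr[sel]),
                 n_bins = as.integer(ng), spacing = c(2, 2, 2),
                 provenance = list(method = "direct", parameter = ng)),
            class = "discretized_voi")
}

in_bounds <- function(v, d) all(v >= 1 & v <= d)

oracle_glcm <- function(arr, ng) {
  d <- dim(arr)
  out <- array(0L, dim = c(ng, ng, 13))
  vox <- which(!is.na(arr), arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    g1 <- arr[v[1], v[2], v[3]]
    for (k in seq_len(nrow(ALL_OFFSETS))) {
      w <- v + ALL_OFFSETS[k, ]
      if (!in_bounds(w, d)) next
      g2 <- arr[w[1], w[2], w[3]]
      if (is.na(g2)) next
      # map offset to its canonical direction index
      off <- ALL_OFFSETS[k, ]
      dir <- which(apply(ORACLE_DIRS, 1, function(u)
        all(u == off) || all(u == -off)))
      out[g1, g2, dir] <- out[g1, g2, dir] + 1L
    }
  }
  out
}

oracle_glrlm <- function(arr, ng) {
  d <- dim(arr)
  maxlen <- max(d)
  out <- array(0L, dim = c(ng, maxlen, 13))
  for (dir in seq_len(13)) {
    u <- ORACLE_DIRS[dir, ]
    # enumerate every maximal run: walk from every voxel that has no
    # same-level predecessor along u
    vox <- which(!is.na(arr), arr.ind = TRUE)
    for (r in seq_len(nrow(vox))) {
      v <- vox[r, ]
      g <- arr[v[1], v[2], v[3]]
      pr <- v - u
      if (in_bounds(pr, d) && !is.na(arr[pr[1], pr[2], pr[3]]) &&
          arr[pr[1], pr[2], pr[3]] == g) next
      len <- 1L
      w <- v + u
      while (in_bounds(w, d) && !is.na(arr[w[1], w[2], w[3]]) &&
             arr[w[1], w[2], w[3]] == g) {
        len <- len + 1L
        w <- w + u
      }
      out[g, len, dir] <- out[g, len, dir] + 1L
    }
  }
  out
}

# connected components of equal level, 26-connectivity, by iterative
# frontier expansion
oracle_zones <- function(arr) {
  d <- dim(arr)
  lab <- array(0L, dim = d)
  nz <- 0L
  repeat {
    seed <- which(!is.na(arr) & lab == 0L)
    if (length(seed) == 0L) break
    nz <- nz + 1L
    members <- seed[1]
    g <- arr[seed[1]]
    repeat {
      grew <- FALSE
      for (m in members) {
        i0 <- m - 1L
        v <- c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2])) + 1L
        for (k in seq_len(nrow(ALL_OFFSETS))) {
          w <- v + ALL_OFFSETS[k, ]
          if (!in_bounds(w, d)) next
          j <- w[1] + d[1] * (w[2] - 1L) + d[1] * d[2] * (w[3] - 1L)
          if (!is.na(arr[j]) && arr[j] == g && !(j %in% members)) {
            members <- c(members, j)
            grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    lab[members] <- nz
  }
  lab
}

oracle_glszm <- function(arr, ng) {
  lab <- oracle_zones(arr)
  nz <- max(lab)
  if (nz == 0L) return(matrix(0L, ng, 1))
  sizes <- tabulate(lab[lab > 0])
  M <- matrix(0L, ng, max(sizes))
  for (z in seq_len(nz)) {
    g <- arr[which(lab == z)[1]]
    M[g, sizes[z]] <- M[g, sizes[z]] + 1L
  }
  M
}

# straight-line Chebyshev distance to the nearest non-VOI voxel,
# out-of-image counting as border
oracle_border_dist <- function(arr) {
  d <- dim(arr)
  out <- array(0L, dim = d)
  vox <- which(!is.na(arr), arr.ind = TRUE)
  holes <- which(is.na(arr), arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    dmin <- min(v, d - v + 1L)  # to out-of-image, per axis
    if (nrow(holes) > 0) {
      dh <- apply(holes, 1, function(h) max(abs(h - v)))
      dmin <- min(dmin, dh)
    }
    out[v[1], v[2], v[3]] <- dmin
  }
  out
}

oracle_gldzm <- function(arr, ng) {
  lab <- oracle_zones(arr)
  dist <- oracle_border_dist(arr)
  nz <- max(lab)
  if (nz == 0L) return(matrix(0L, ng, 1))
  zd <- vapply(seq_len(nz), function(z) min(dist[lab == z]), integer(1))
  M <- matrix(0L, ng, max(zd))
  for (z in seq_len(nz)) {
    g <- arr[which(lab == z)[1]]
    M[g, zd[z]] <- M[g, zd[z]] + 1L
  }
  M
}

oracle_ngtdm <- function(arr, ng) {
  d <- dim(arr)
  n <- numeric(ng); s <- numeric(ng)
  vox <- which(!is.na(arr), arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    g <- arr[v[1], v[2], v[3]]
    nb <- c()
    for (k in seq_len(nrow(ALL_OFFSETS))) {
      w <- v + ALL_OFFSETS[k, ]
      if (!in_bounds(w, d)) next
      gg <- arr[w[1], w[2], w[3]]
      if (!is.na(gg)) nb <- c(nb, gg)
    }
    if (length(nb) == 0L) next
    n[g] <- n[g] + 1
    s[g] <- s[g] + abs(g - mean(nb))
  }
  list(n = n, s = s)
}

oracle_ngldm <- function(arr, ng, alpha = 0L) {
  d <- dim(arr)
  M <- matrix(0L, ng, 27)
  vox <- which(!is.na(arr), arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- vox[r, ]
    g <- arr[v[1], v[2], v[3]]
    kdep <- 0L
    for (k in seq_len(nrow(ALL_OFFSETS))) {
      w <- v + ALL_OFFSETS[k, ]
      if (!in_bounds(w, d)) next
      gg <- arr[w[1], w[2], w[3]]
      if (!is.na(gg) && abs(gg - g) <= alpha) kdep <- kdep + 1L
    }
    M[g, kdep + 1L] <- M[g, kdep + 1L] + 1L
  }
  M
}

# pad the second (run-length / size / distance) axis of two count arrays
# to a common width before comparison; trailing all-zero columns are
# representation, not content
pad_axis2 <- function(A, m) {
  d <- dim(A)
  if (d[2] >= m) return(A)
  if (length(d) == 2) cbind(A, matrix(0L, d[1], m - d[2]))
  else {
    out <- array(0L, dim = c(d[1], m, d[3]))
    out[, seq_len(d[2]), ] <- A
    out
  }
}

same_counts <- function(A, B) {
  m <- max(dim(A)[2], dim(B)[2])
  identical(as.vector(pad_axis2(A, m)), as.vector(pad_axis2(B, m)))
}

# trapezoidal ROC integration, an independent route to the AUC
oracle_auc_trapezoid <- function(scores, labels) {
  y <- as.integer(factor(labels)) - 1L
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[y == 1] >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores[y == 0] >= t), numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}
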