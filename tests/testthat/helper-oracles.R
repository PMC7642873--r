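# Independent brute-force oracles and small fixture builders. These
# deliberately use naive enumeration (explicit voxel loops, rle over extracted
# lattice lines, iterative set-growing for zones) so they share no code path
# with the package kernels.

oracle_dirs <- matrix(c(1,0,0, 0,1,0, 0,0,1,
                        1,1,0, 1,-1,0, 1,0,1, 1,0,-1, 0,1,1, 0,1,-1,
                        1,1,1, 1,1,-1, 1,-1,1, 1,-1,-1),
                      ncol = 3, byrow = TRUE)

# random discretized ROI built directly (no package code involved)
rand_droi <- function(dims, ng, seed, p_roi = 0.7) {
  set.seed(seed)
  lv <- array(0L, dims)
  roi <- array(runif(prod(dims)) < p_roi, dims)
  if (!any(roi)) roi[1] <- TRUE
  lv[roi] <- sample.int(ng, sum(roi), replace = TRUE)
  ng_eff <- max(lv)
  structure(list(levels = lv, ng = as.integer(ng_eff), bin_width = 1,
                 spacing = c(1, 1, 1)), class = "discretized_roi")
}

inb <- function(v, d) all(v >= 1 & v <= d)

oracle_glcm <- function(lv, ng) {
  d <- dim(lv)
  out <- array(0, c(ng, ng, 13))
  for (dd in 1:13) {
    off <- oracle_dirs[dd, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lv[x, y, z]
      if (a == 0) next
      for (sg in c(1, -1)) {
        q <- c(x, y, z) + sg * off
        if (!inb(q, d)) next
        b <- lv[q[1], q[2], q[3]]
        if (b == 0) next
        out[a, b, dd] <- out[a, b, dd] + 1
      }
    }
  }
  out
}

oracle_glrlm <- function(lv, ng) {
  d <- dim(lv)
  maxlen <- max(d)
  out <- array(0, c(ng, maxlen, 13))
  for (dd in 1:13) {
    off <- oracle_dirs[dd, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      # line start: predecessor out of bounds
      if (inb(c(x, y, z) - off, d)) next
      seqv <- integer(0)
      q <- c(x, y, z)
      while (inb(q, d)) {
        seqv <- c(seqv, lv[q[1], q[2], q[3]])
        q <- q + off
      }
      r <- rle(seqv)
      for (k in seq_along(r$lengths)) {
        if (r$values[k] == 0) next
        out[r$values[k], r$lengths[k], dd] <- out[r$values[k], r$lengths[k], dd] + 1
      }
    }
  }
  out
}

oracle_glszm <- function(lv, ng) {
  d <- dim(lv)
  idx <- which(lv > 0)
  coords <- which(array(lv > 0, d), arr.ind = TRUE)
  assigned <- rep(FALSE, length(idx))
  sizes <- list()
  key <- function(v) paste(v, collapse = ",")
  pos <- lapply(seq_len(nrow(coords)), function(i) coords[i, ])
  lookup <- setNames(seq_along(pos), vapply(pos, key, ""))
  for (i in seq_along(pos)) {
    if (assigned[i]) next
    lev <- lv[coords[i, 1], coords[i, 2], coords[i, 3]]
    zone <- i
    assigned[i] <- TRUE
    frontier <- list(pos[[i]])
    count <- 1
    while (length(frontier)) {
      nf <- list()
      for (p in frontier) {
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          if (dx == 0 && dy == 0 && dz == 0) next
          q <- p + c(dx, dy, dz)
          if (!inb(q, d)) next
          if (lv[q[1], q[2], q[3]] != lev) next
          j <- lookup[[key(q)]]
          if (!assigned[j]) {
            assigned[j] <- TRUE
            count <- count + 1
            nf <- c(nf, list(q))
          }
        }
      }
      frontier <- nf
    }
    sizes[[length(sizes) + 1]] <- c(lev, count)
  }
  maxs <- max(vapply(sizes, `[`, 0, 2))
  out <- matrix(0, ng, maxs)
  for (s in sizes) out[s[1], s[2]] <- out[s[1], s[2]] + 1
  out
}

oracle_gldm <- function(lv, ng, alpha = 0) {
  d <- dim(lv)
  out <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!inb(q, d)) next
      b <- lv[q[1], q[2], q[3]]
      if (b != 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    out[a, dep + 1] <- out[a, dep + 1] + 1
  }
  out
}

oracle_ngtdm <- function(lv, ng) {
  d <- dim(lv)
  out <- matrix(0, ng, 2)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (a == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!inb(q, d)) next
      b <- lv[q[1], q[2], q[3]]
      if (b != 0) nb <- c(nb, b)
    }
    if (length(nb)) {
      out[a, 1] <- out[a, 1] + 1
      out[a, 2] <- out[a, 2] + abs(a - mean(nb))
    }
  }
  out
}

# O(n^2) pair-counting AUC
auc_bruteforce <- function(labels, scores) {
  y <- as.character(labels) == "codeleted"
  pos <- scores[y]; neg <- scores[!y]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# small helper volumes
ball_mask <- function(n = 25, r = 10, spacing = c(1, 1, 1)) {
  g <- seq_len(n) - (n + 1) / 2
  M <- outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2
  roi_mask(array(as.integer(M), c(n, n, n)), spacing)
}

rand_volume <- function(dims, seed, spacing = c(1, 1, 1)) {
  set.seed(seed)
  image_volume(array(rnorm(prod(dims)), dims), spacing)
}
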