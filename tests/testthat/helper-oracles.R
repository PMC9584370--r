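# Independent brute-force oracles and geometric fixtures used across tests.
# Everything here is deliberately written with a different algorithmic route
# than the package implementation it checks.

# ball mask as a label_volume, centered on the lattice
ball_volume <- function(radius, spacing, label = c(globe = 1L), margin = 2) {
  n <- 2L * as.integer(ceiling((radius + margin) / spacing)) + 1L
  ax <- (seq_len(n) - 1) * spacing - (n - 1) / 2 * spacing
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  label_volume(array(as.integer(r2 <= radius^2), c(n, n, n)), spacing,
               origin = rep(-(n - 1) / 2 * spacing, 3), label_map = label)
}

# icosphere: subdivided icosahedron projected to the sphere (watertight by
# construction), independent of the package's surface extraction
icosphere <- function(radius = 1, subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v * radius / sqrt(rowSums(v^2))
  triangle_mesh(v, f, component = "sphere")
}

# Dice coefficient between two binary label volumes on commensurate lattices
dice_between <- function(vol_a, vol_b) {
  h <- vol_a$spacing[1]
  stopifnot(abs(vol_b$spacing[1] - h) < 1e-9)
  off <- (vol_b$origin - vol_a$origin) / h
  stopifnot(max(abs(off - round(off))) < 1e-6)
  off <- round(off)
  db <- dim(vol_b$voxels)
  ia <- which(vol_a$voxels > 0, arr.ind = TRUE)
  ib <- sweep(ia, 2, off)  # index of the same world point in b
  ok <- ib[, 1] >= 1 & ib[, 2] >= 1 & ib[, 3] >= 1 &
    ib[, 1] <= db[1] & ib[, 2] <= db[2] & ib[, 3] <= db[3]
  inter <- sum(vol_b$voxels[ib[ok, , drop = FALSE]] > 0)
  2 * inter / (sum(vol_a$voxels > 0) + sum(vol_b$voxels > 0))
}

# brute-force gap fill on small grids: full distance scan per background
# voxel, same rule as close_gaps but via explicit per-component argmin with
# integer squared distances and lexicographic displacement tie-break
oracle_fill_gaps <- function(vol, max_gap) {
  h <- vol$spacing[1]
  labs <- sort(unique(vol$voxels[vol$voxels > 0]))
  d <- dim(vol$voxels)
  out <- vol$voxels
  comp_idx <- lapply(labs, function(l) which(vol$voxels == l, arr.ind = TRUE))
  bg <- which(vol$voxels == 0, arr.ind = TRUE)
  r2max <- (max_gap / h)^2 + 1e-9
  for (b in seq_len(nrow(bg))) {
    p <- bg[b, ]
    best <- lapply(comp_idx, function(ci) {
      dx <- sweep(ci, 2, p)                 # displacement toward component
      n2 <- rowSums(dx^2)
      m <- min(n2)
      cand <- dx[n2 == m, , drop = FALSE]
      ord <- order(cand[, 1], cand[, 2], cand[, 3])
      list(d2 = m, off = cand[ord[1], ])
    })
    d2s <- vapply(best, `[[`, numeric(1), "d2")
    o1 <- which.min(d2s)                    # ties -> lower label (order)
    if (d2s[o1] > r2max) next
    rest <- setdiff(seq_along(labs), o1)
    o2 <- rest[which.min(d2s[rest])]
    if (length(o2) == 0 || d2s[o2] > r2max) next
    if (sum(best[[o1]]$off * best[[o2]]$off) < -1e-9)
      out[p[1], p[2], p[3]] <- labs[o1]
  }
  res <- vol
  res$voxels <- out
  res
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(a, b)
  mn2 <- n * (length(pooled) - n) / 2
  p <- if (u_obs > mn2) 2 * mean(us >= u_obs - 1e-9)
       else 2 * mean(us <= u_obs + 1e-9)
  min(p, 1)
}

# two-sided Fisher exact p by full hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact Spearman permutation p by recursive enumeration of raw-y permutations
oracle_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  pm <- perms(y)
  rhos <- apply(pm, 1, function(yy) stats::cor(x, yy, method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# type-7 quartiles by hand: linear interpolation between order statistics
oracle_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  q <- function(p) {
    hpos <- (n - 1) * p + 1
    lo <- floor(hpos); hi <- ceiling(hpos)
    x[lo] + (hpos - lo) * (x[hi] - x[lo])
  }
  c(q1 = q(0.25), med = q(0.5), q3 = q(0.75))
}

# small, quick-to-generate phantom spec for unit tests; any field can be
# overridden by name
small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(globe_radius = 8, plate_extent = c(18, 10, 1),
         inner_bleb_thickness = 2, outer_bleb_thickness = 2,
         voxel_spacing = 0.4),
    list(...))
  do.call(phantom_spec, args)
}
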