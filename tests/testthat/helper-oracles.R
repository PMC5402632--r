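# Brute-force reference implementations used as independent oracles.
# All of them work by direct voxel/neighbour enumeration (arrayInd scatter,
# breadth-first frontiers, explicit offset balls) and share no code with the
# package's shift-based morphology, C++ labeling or distance transform.

conn_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(du = -1:1, dv = -1:1, dw = -1:1))
  s <- abs(g[, 1]) + abs(g[, 2]) + abs(g[, 3])
  lim <- switch(connectivity, face = 1L, face_edge = 2L, face_edge_vertex = 3L)
  g[s >= 1 & s <= lim, , drop = FALSE]
}

scatter_offsets <- function(a, offs) {
  d <- dim(a)
  out <- array(FALSE, d)
  idx <- which(a)
  if (length(idx) == 0L) return(out)
  pts <- arrayInd(idx, d)
  for (k in seq_len(nrow(offs))) {
    np <- cbind(pts[, 1] + offs[k, 1], pts[, 2] + offs[k, 2],
                pts[, 3] + offs[k, 3])
    ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
      np[, 3] >= 1 & np[, 3] <= d[3]
    if (!any(ok)) next
    ni <- np[ok, 1] + d[1] * (np[ok, 2] - 1L) + d[1] * d[2] * (np[ok, 3] - 1L)
    out[ni] <- TRUE
  }
  out
}

oracle_dilate_cross <- function(a, steps = 1L) {
  offs <- rbind(c(0, 0, 0), conn_offsets("face"))
  for (i in seq_len(steps)) a <- scatter_offsets(a, offs)
  a
}

oracle_erode_cross <- function(a, steps = 1L) {
  d <- dim(a)
  offs <- conn_offsets("face")
  for (i in seq_len(steps)) {
    idx <- which(a)
    if (length(idx) == 0L) break
    pts <- arrayInd(idx, d)
    keep <- rep(TRUE, length(idx))
    for (k in seq_len(nrow(offs))) {
      np <- cbind(pts[, 1] + offs[k, 1], pts[, 2] + offs[k, 2],
                  pts[, 3] + offs[k, 3])
      inside <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 &
        np[, 2] <= d[2] & np[, 3] >= 1 & np[, 3] <= d[3]
      ni <- np[inside, 1] + d[1] * (np[inside, 2] - 1L) +
        d[1] * d[2] * (np[inside, 3] - 1L)
      ok <- inside          # out-of-lattice neighbour counts as background
      ok[inside] <- a[ni]
      keep <- keep & ok
    }
    out <- array(FALSE, d)
    out[idx[keep]] <- TRUE
    a <- out
  }
  a
}

# Breadth-first connected-component labeling; seeds in column-major scan order.
oracle_label <- function(a, connectivity = "face") {
  d <- dim(a)
  offs <- conn_offsets(connectivity)
  lab <- array(0L, d)
  cur <- 0L
  for (i in which(a)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    frontier <- i
    while (length(frontier)) {
      pts <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        np <- cbind(pts[, 1] + offs[k, 1], pts[, 2] + offs[k, 2],
                    pts[, 3] + offs[k, 3])
        ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 &
          np[, 2] <= d[2] & np[, 3] >= 1 & np[, 3] <= d[3]
        if (!any(ok)) next
        ni <- np[ok, 1] + d[1] * (np[ok, 2] - 1L) +
          d[1] * d[2] * (np[ok, 3] - 1L)
        ni <- ni[a[ni] & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- cur
          nxt <- c(nxt, ni)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

oracle_fill_cavities <- function(a) {
  d <- dim(a)
  bg <- !a
  border <- array(FALSE, d)
  border[1, , ] <- TRUE; border[d[1], , ] <- TRUE
  border[, 1, ] <- TRUE; border[, d[2], ] <- TRUE
  border[, , 1] <- TRUE; border[, , d[3]] <- TRUE
  reached <- array(FALSE, d)
  frontier <- which(bg & border)
  reached[frontier] <- TRUE
  offs <- conn_offsets("face")
  while (length(frontier)) {
    pts <- arrayInd(frontier, d)
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      np <- cbind(pts[, 1] + offs[k, 1], pts[, 2] + offs[k, 2],
                  pts[, 3] + offs[k, 3])
      ok <- np[, 1] >= 1 & np[, 1] <= d[1] & np[, 2] >= 1 & np[, 2] <= d[2] &
        np[, 3] >= 1 & np[, 3] <= d[3]
      if (!any(ok)) next
      ni <- np[ok, 1] + d[1] * (np[ok, 2] - 1L) + d[1] * d[2] * (np[ok, 3] - 1L)
      ni <- ni[bg[ni] & !reached[ni]]
      if (length(ni)) {
        reached[ni] <- TRUE
        nxt <- c(nxt, ni)
      }
    }
    frontier <- unique(nxt)
  }
  a | (bg & !reached)
}

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(du = -r:r, dv = -r:r, dw = -r:r))
  g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= radius^2 + 1e-9, , drop = FALSE]
}

oracle_euclid_dilate <- function(a, radius) {
  if (!any(a)) return(a)
  scatter_offsets(a, ball_offsets(radius))
}

oracle_pad <- function(a, n) {
  d <- dim(a)
  out <- array(FALSE, d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- a
  out
}

oracle_crop <- function(a, n, d) {
  a[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])]
}

oracle_euclid_erode <- function(a, radius) {
  n <- as.integer(ceiling(radius)) + 1L
  p <- oracle_pad(a, n)
  bad <- oracle_euclid_dilate(!p, radius)
  oracle_crop(p & !bad, n, dim(a))
}

oracle_close_and_fill <- function(a, steps) {
  d <- dim(a)
  pad <- steps + 1L
  p <- oracle_pad(a, pad)
  p <- oracle_euclid_dilate(p, steps)
  p <- oracle_fill_cavities(p)
  p <- oracle_euclid_erode(p, steps)
  p <- oracle_fill_cavities(p)
  oracle_crop(p, pad, d)
}

oracle_build_mask <- function(solid, thickness) {
  interior <- oracle_erode_cross(solid, thickness)
  shell <- solid & !interior
  peri <- shell & scatter_offsets(!solid, rbind(c(0, 0, 0), conn_offsets("face")))
  endo <- shell & scatter_offsets(interior, rbind(c(0, 0, 0), conn_offsets("face")))
  list(shell = shell, peri = peri, endo = endo, interior = interior)
}

# Full detection contract by direct iteration: (a) cortical bone, (b) bone
# dilation, (c) void, (d) components containing voxels of both faces,
# (e) restoration clipped to shell & !bone, (f) relabel + size floor.
oracle_detect <- function(bone, shell, peri, endo, r = 1L, min_vox = 20L,
                          connectivity = "face") {
  cortical <- bone & shell
  void <- shell & !oracle_dilate_cross(cortical, r)
  lab <- oracle_label(void, connectivity)
  keep <- integer(0)
  if (max(lab) > 0L) {
    for (l in seq_len(max(lab))) {
      m <- lab == l
      if (any(m & peri) && any(m & endo)) keep <- c(keep, l)
    }
  }
  kept <- array(lab %in% keep & lab > 0L, dim(lab))
  restored <- oracle_dilate_cross(kept, r) & shell & !bone
  fin <- oracle_label(restored, connectivity)
  if (max(fin) > 0L) {
    sizes <- tabulate(fin[fin > 0L], max(fin))
    drop <- which(sizes < min_vox)
    fin[array(fin %in% drop, dim(fin))] <- 0L
  }
  fin
}

# Components of a label array as a canonical list of sorted voxel-index sets,
# ordered by their smallest index (label names irrelevant).
label_sets <- function(lab) {
  ks <- sort(unique(lab[lab > 0]))
  sets <- lapply(ks, function(k) sort(which(lab == k)))
  if (length(sets) > 1L) sets <- sets[order(vapply(sets, min, 0))]
  sets
}

# Random blobby solid for oracle equivalence runs: union of a few boxes and
# balls inside a lattice of the given dimensions.
random_solid <- function(d, n_blobs = 2L) {
  a <- array(FALSE, d)
  I1 <- slice.index(a, 1); I2 <- slice.index(a, 2); I3 <- slice.index(a, 3)
  for (b in seq_len(n_blobs)) {
    if (stats::runif(1) < 0.5) {
      lo <- pmax(2L, sapply(d, function(n) sample.int(n - 3L, 1L)))
      hi <- pmin(d - 1L, lo + sapply(d, function(n) sample.int(max(2L, n %/% 2L), 1L)))
      a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    } else {
      ctr <- sapply(d, function(n) stats::runif(1, 3, n - 2))
      rad <- stats::runif(1, 2, max(3, min(d) / 3))
      a <- a | ((I1 - ctr[1])^2 + (I2 - ctr[2])^2 + (I3 - ctr[3])^2 <= rad^2)
    }
  }
  a
}

# Random bone configuration on a solid: the solid's wall with carved notches
# and scattered single-voxel pores.
random_bone <- function(solid, d) {
  bone <- solid
  n_carve <- sample.int(3L, 1L)
  for (i in seq_len(n_carve)) {
    lo <- sapply(d, function(n) sample.int(n, 1L))
    sz <- sample.int(4L, 3L, replace = TRUE)
    hi <- pmin(d, lo + sz)
    bone[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- FALSE
  }
  pores <- which(solid)
  if (length(pores) > 10L)
    bone[sample(pores, min(10L, length(pores) %/% 10L))] <- FALSE
  bone
}
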