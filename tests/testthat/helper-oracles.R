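# Independent oracles and fixture builders shared across tests. Both ring
# oracles avoid the package's per-label distance-transform path entirely.

# Quadratic brute force: for every background pixel, scan every nuclear
# pixel. Exact, O(HW * |nuclei|); only for small masks.
ring_oracle_quad <- function(nuclei, width) {
  H <- nrow(nuclei); W <- ncol(nuclei)
  rings <- matrix(0L, H, W)
  np <- which(nuclei > 0L)
  if (!length(np)) return(rings)
  nr <- (np - 1L) %% H + 1L
  nc <- (np - 1L) %/% H + 1L
  nl <- nuclei[np]
  for (i in which(nuclei == 0L)) {
    r <- (i - 1L) %% H + 1L
    c <- (i - 1L) %/% H + 1L
    d2 <- (nr - r)^2 + (nc - c)^2
    j <- which(d2 <= width^2)
    if (length(j)) {
      dmin <- min(d2[j])
      rings[i] <- min(nl[j][d2[j] == dmin])  # smaller label wins ties
    }
  }
  rings
}

# Disk-stamping brute force: every nuclear pixel stamps a Euclidean disk of
# candidate (distance, label) pairs; each background pixel keeps the
# nearest, ties to the smaller label (labels processed in ascending order
# with strict-improvement updates).
ring_oracle_stamp <- function(nuclei, width) {
  H <- nrow(nuclei); W <- ncol(nuclei)
  off <- expand.grid(dr = -width:width, dc = -width:width)
  off$d <- sqrt(off$dr^2 + off$dc^2)
  off <- off[off$d <= width, ]
  best <- matrix(Inf, H, W)
  rings <- matrix(0L, H, W)
  for (l in seq_len(max(nuclei))) {
    pix <- which(nuclei == l, arr.ind = TRUE)
    if (!nrow(pix)) next
    for (k in seq_len(nrow(off))) {
      tr <- pix[, 1] + off$dr[k]
      tc <- pix[, 2] + off$dc[k]
      ok <- tr >= 1L & tr <= H & tc >= 1L & tc <= W
      if (!any(ok)) next
      idx <- (tc[ok] - 1L) * H + tr[ok]
      upd <- idx[nuclei[idx] == 0L & best[idx] > off$d[k]]
      if (length(upd)) {
        rings[upd] <- l
        best[upd] <- off$d[k]
      }
    }
  }
  rings
}

# Random mask of non-overlapping disks with contiguous labels in raster-scan
# order of first pixels (computed here, independently of the package).
random_disk_mask <- function(H, W, n_disks, radius_range = c(4, 9),
                             seed = 1L) {
  set.seed(seed)
  mask <- matrix(0L, H, W)
  centers <- matrix(NA_real_, 0, 2)
  radii <- numeric(0)
  tries <- 0L
  while (length(radii) < n_disks && tries < 5000L) {
    tries <- tries + 1L
    r <- runif(1, radius_range[1], radius_range[2])
    cr <- runif(1, r + 1, H - r)
    cc <- runif(1, r + 1, W - r)
    if (nrow(centers) &&
        min(sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2) -
            (radii + r)) < 2) next
    centers <- rbind(centers, c(cr, cc))
    radii <- c(radii, r)
  }
  for (k in seq_along(radii)) {
    px <- which((row(mask) - centers[k, 1])^2 +
                (col(mask) - centers[k, 2])^2 <= radii[k]^2)
    mask[px] <- k
  }
  # relabel in raster-scan (row-major) order of first pixels
  idx <- which(mask > 0L)
  key <- ((idx - 1L) %% H) * W + (idx - 1L) %/% H
  first <- vapply(split(key, mask[idx]), min, numeric(1))
  remap <- integer(max(mask))
  remap[as.integer(names(first))[order(first)]] <- seq_along(first)
  mask[idx] <- remap[mask[idx]]
  mask
}

# Uniform RGB image at the given per-channel levels, values already on the
# 8-bit grid so PNG round trips are exact.
uniform_image <- function(H, W, rgb = c(1, 1, 1)) {
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- round(rgb[ch] * 255) / 255
  rgb_image(px, dtype_scale = 255)
}
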