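# Relabel nonzero components contiguously 1..N in raster-scan (row-major)
# order of each object's first pixel; labels become deterministic geometry.
relabel_raster_order <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0L)
  if (!length(idx)) return(matrix(0L, H, W))
  old <- lab[idx]
  ri <- (idx - 1L) %% H
  ci <- (idx - 1L) %/% H
  key <- ri * W + ci                       # row-major scan position
  first <- vapply(split(key, old), min, numeric(1))
  ord <- order(first)                      # old labels sorted by first pixel
  map <- integer(max(old))
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- matrix(0L, H, W)
  out[idx] <- map[old]
  out
}

# 8-connected labeling. EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a union-find pass over
# the diagonal adjacencies.
label_components <- function(bw) {
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n > 1L) {
    H <- nrow(lab); W <- ncol(lab)
    a1 <- lab[-H, -W]; b1 <- lab[-1, -1]   # down-right diagonal
    a2 <- lab[-H, -1]; b2 <- lab[-1, -W]   # down-left diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs)) {
      parent <- seq_len(n)
      find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[] <- c(0L, root)[lab + 1L]
    }
  }
  relabel_raster_order(lab)
}

# TRUE iff nonzero labels are exactly 1..max (contiguous).
labels_contiguous <- function(lab) {
  u <- sort(unique(as.integer(lab[lab > 0L])))
  identical(u, seq_len(length(u))) || length(u) == 0L
}

#' Segment hematoxylin-stained nuclei
#'
#' Thresholds the nuclear map (Otsu by default, or a fixed threshold), fills
#' holes left by chromatin texture, optionally splits touching nuclei by
#' watershed on the negated Euclidean distance transform, removes objects
#' outside the configured area bounds, optionally removes border-touching
#' objects (whose area is censored), and relabels contiguously `1..N` in
#' raster-scan order of object first pixels, so label geometry is
#' deterministic.
#'
#' @param maps A `"channel_maps"` object from [build_maps()].
#' @param config An [analysis_config()].
#' @return An integer H x W label matrix (0 = background). A contrast-free
#'   (constant) nuclear map yields an empty mask with a warning, not an
#'   error.
#' @export
segment_nuclei <- function(maps, config = analysis_config()) {
  if (!inherits(maps, "channel_maps")) stop("expected channel_maps")
  x <- maps$nuclear_map
  H <- nrow(x); W <- ncol(x)
  if (diff(range(x)) < 1e-12) {
    warning("nuclear map has no contrast; returning an empty mask")
    return(matrix(0L, H, W))
  }
  thr <- if (config$threshold_method == "fixed") config$fixed_threshold
         else EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  bw <- x > thr
  if (!any(bw)) {
    warning("no pixels above threshold; returning an empty mask")
    return(matrix(0L, H, W))
  }
  bw <- EBImage::imageData(EBImage::fillHull(bw * 1L)) > 0

  if (config$split_touching) {
    d <- EBImage::distmap(bw * 1L)
    # Watershed seeds are local maxima of the distance map; `ext` is the
    # seed-separation radius, half the side of the smallest admissible
    # nucleus.
    ext <- max(1L, as.integer(floor(sqrt(config$min_nucleus_area_px) / 2)))
    lab <- EBImage::imageData(EBImage::watershed(d, tolerance = 1, ext = ext))
    storage.mode(lab) <- "integer"
  } else {
    lab <- label_components(bw)
  }

  n <- max(lab)
  if (n > 0L) {
    counts <- tabulate(lab[lab > 0L], nbins = n)
    drop <- counts < config$min_nucleus_area_px
    if (!is.null(config$max_nucleus_area_px))
      drop <- drop | counts > config$max_nucleus_area_px
    if (config$exclude_border) {
      border <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
      drop[border[border > 0L]] <- TRUE
    }
    if (any(drop)) lab[lab %in% which(drop)] <- 0L
  }
  relabel_raster_order(lab)
}

#' Build the perinuclear ring masks
#'
#' The ring of a nucleus is the set of background pixels within Euclidean
#' distance `ring_width_px` of any of its pixels (disk-structuring-element
#' dilation minus the nuclei themselves). Every ring pixel is assigned the
#' label of its nearest nucleus; equidistant pixels go to the smaller label.
#' Rings therefore never overlap each other or any nucleus, which is what
#' makes the perinuclear (cytoplasmic, non-nuclear) signal well defined per
#' cell.
#'
#' Implementation: per-label exact Euclidean distance transform restricted
#' to the label's padded bounding box, with strict-improvement updates in
#' ascending label order (realizing the smaller-label tie-break).
#'
#' @param nuclei Integer label matrix with contiguous labels `1..N`.
#' @param ring_width_px Positive integer ring width; default 7, the
#'   reference perinuclear ring.
#' @return An object of class `"ring_masks"`: list with `nuclei`, `rings`
#'   (integer label matrix, same shape) and `ring_width_px`.
#' @export
make_perinuclear_rings <- function(nuclei, ring_width_px = 7L) {
  ring_width_px <- as.integer(ring_width_px)
  if (length(ring_width_px) != 1L || is.na(ring_width_px) ||
      ring_width_px < 1L)
    stop("ring_width_px must be a positive integer (>= 1)")
  if (!labels_contiguous(nuclei))
    stop("contract error: nuclear labels must be contiguous 1..N")
  H <- nrow(nuclei); W <- ncol(nuclei)
  storage.mode(nuclei) <- "integer"
  n <- max(nuclei)
  rings <- matrix(0L, H, W)
  if (n == 0L)
    return(structure(list(nuclei = nuclei, rings = rings,
                          ring_width_px = ring_width_px),
                     class = "ring_masks"))
  best <- matrix(Inf, H, W)
  pad <- ring_width_px + 1L
  for (l in seq_len(n)) {
    pix <- which(nuclei == l, arr.ind = TRUE)
    r0 <- max(1L, min(pix[, 1]) - pad); r1 <- min(H, max(pix[, 1]) + pad)
    c0 <- max(1L, min(pix[, 2]) - pad); c1 <- min(W, max(pix[, 2]) + pad)
    sub <- nuclei[r0:r1, c0:c1, drop = FALSE]
    fg <- matrix(1L, nrow(sub), ncol(sub))
    fg[sub == l] <- 0L
    d <- EBImage::imageData(EBImage::distmap(fg))  # distance to nucleus l
    cand <- sub == 0L & d <= ring_width_px
    if (!any(cand)) next
    bsub <- best[r0:r1, c0:c1, drop = FALSE]
    upd <- cand & d < bsub                         # strict: ties keep smaller l
    if (any(upd)) {
      rsub <- rings[r0:r1, c0:c1, drop = FALSE]
      rsub[upd] <- l
      bsub[upd] <- d[upd]
      rings[r0:r1, c0:c1] <- rsub
      best[r0:r1, c0:c1] <- bsub
    }
  }
  structure(list(nuclei = nuclei, rings = rings,
                 ring_width_px = ring_width_px),
            class = "ring_masks")
}

#' @export
print.ring_masks <- function(x, ...) {
  cat(sprintf(
    "Ring masks: %d nuclei, ring width %d px, %d ring pixels total\n",
    max(x$nuclei), x$ring_width_px, sum(x$rings > 0L)))
  invisible(x)
}
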