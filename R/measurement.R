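#' Measure per-cell nuclear area and perinuclear signal
#'
#' For every nucleus label: the nuclear pixel count (`area_px`, the ploidy
#' surrogate), the 0-based centroid, the ring pixel count, and the mean and
#' integrated signal over the ring pixels (the ER-stress surrogate when the
#' chromogen reports phospho-eIF2-alpha). A nucleus whose ring is empty
#' (fully enclosed by neighbours) keeps its record with
#' `perinuclear_mean = NA`.
#'
#' @param pair A `"ring_masks"` object from [make_perinuclear_rings()].
#' @param signal_map Matrix in \[0,1\], same shape as the masks (typically
#'   `build_maps(...)$signal_map`).
#' @param pixel_size_um Optional micrometers per pixel;
#'   `area_um2 = area_px * pixel_size_um^2` when given.
#' @return A data frame with columns `label`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `ring_pixels`, `perinuclear_mean`,
#'   `perinuclear_integrated`, `border_flag`, sorted by label.
#' @export
measure_cells <- function(pair, signal_map, pixel_size_um = NULL) {
  if (!inherits(pair, "ring_masks")) stop("expected ring_masks")
  nuclei <- pair$nuclei; rings <- pair$rings
  if (!identical(dim(signal_map), dim(nuclei)))
    stop("signal_map shape does not match the masks")
  H <- nrow(nuclei); W <- ncol(nuclei)
  n <- max(nuclei)
  if (n == 0L)
    return(data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), ring_pixels = integer(0),
                      perinuclear_mean = numeric(0),
                      perinuclear_integrated = numeric(0),
                      border_flag = logical(0)))

  idx <- which(nuclei > 0L)
  labs <- nuclei[idx]
  area <- tabulate(labs, nbins = n)
  ri <- (idx - 1L) %% H            # 0-based row
  ci <- (idx - 1L) %/% H           # 0-based col
  centroid_row <- as.numeric(rowsum(ri, labs)) / area
  centroid_col <- as.numeric(rowsum(ci, labs)) / area

  ridx <- which(rings > 0L)
  rlabs <- rings[ridx]
  ring_pixels <- tabulate(rlabs, nbins = n)
  integrated <- numeric(n)
  if (length(ridx)) {
    s <- rowsum(signal_map[ridx], rlabs)
    integrated[as.integer(rownames(s))] <- s[, 1]
  }
  peri_mean <- ifelse(ring_pixels > 0L, integrated / ring_pixels, NA_real_)

  border <- unique(c(nuclei[1, ], nuclei[H, ], nuclei[, 1], nuclei[, W]))
  border_flag <- seq_len(n) %in% border[border > 0L]

  area_um2 <- if (is.null(pixel_size_um)) rep(NA_real_, n)
              else area * pixel_size_um^2

  data.frame(label = seq_len(n), area_px = area, area_um2 = area_um2,
             centroid_row = centroid_row, centroid_col = centroid_col,
             ring_pixels = ring_pixels, perinuclear_mean = peri_mean,
             perinuclear_integrated = integrated, border_flag = border_flag)
}

# Equal-width histogram spanning the observed range; counts always sum to
# length(x). A zero-width range degenerates to one unit-wide bin.
hist_fixed <- function(x, bins = 30L) {
  rng <- range(x)
  if (diff(rng) == 0) {
    edges <- rng[1] + c(-0.5, 0.5)
    return(list(edges = edges, counts = length(x)))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                          bins), nbins = bins)
  list(edges = edges, counts = counts)
}

#' Group-level summary of per-cell measurements
#'
#' Means and SEMs (sample sd / sqrt(n); undefined for n < 2) of nuclear area
#' and perinuclear signal, plus equal-width histograms of both. Cells with
#' an empty ring have no defined signal: they are excluded from the signal
#' summaries (their count is reported in `n_signal_excluded`) but retained
#' in area summaries.
#'
#' @param records Per-cell data frame from [measure_cells()].
#' @param bins Number of equal-width histogram bins (default 30).
#' @param statistic Which per-cell signal feeds the summary: `"mean"`
#'   (default) or `"integrated"`.
#' @return An object of class `"group_summary"`.
#' @export
summarize_cells <- function(records, bins = 30L,
                            statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  if (!nrow(records)) stop("contract error: empty group, nothing to summarize")
  n <- nrow(records)
  area <- records$area_px
  sig_all <- if (statistic == "mean") records$perinuclear_mean
             else records$perinuclear_integrated
  sig_all[records$ring_pixels == 0L] <- NA_real_
  sig <- sig_all[!is.na(sig_all)]
  sem <- function(v) if (length(v) >= 2L) stats::sd(v) / sqrt(length(v))
                     else NA_real_
  structure(list(
    n = n,
    mean_area = mean(area),
    sem_area = sem(area),
    n_signal = length(sig),
    n_signal_excluded = n - length(sig),
    mean_signal = if (length(sig)) mean(sig) else NA_real_,
    sem_signal = sem(sig),
    signal_statistic = statistic,
    area_histogram = hist_fixed(area, bins),
    signal_histogram = if (length(sig)) hist_fixed(sig, bins) else NULL),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group of %d cells\n", x$n))
  cat(sprintf("  nuclear area:      %.2f +/- %.2f px (mean +/- SEM)\n",
              x$mean_area, x$sem_area))
  cat(sprintf("  perinuclear %s: %.4f +/- %.4f (%d cells; %d excluded)\n",
              x$signal_statistic, x$mean_signal, x$sem_signal,
              x$n_signal, x$n_signal_excluded))
  invisible(x)
}

#' One-tailed Student's t test between two cell groups
#'
#' Two-sample t test on nuclear area or perinuclear signal, pooled variance
#' by default (Student's test proper; Welch available by flag). One-tailed:
#' `alternative = "greater"` tests whether group `a` exceeds group `b`.
#' Cells without a defined signal are dropped from signal comparisons.
#'
#' @param a,b Per-cell data frames from [measure_cells()].
#' @param variable `"area"` or `"signal"`.
#' @param alternative `"greater"` or `"less"` (a vs b).
#' @param statistic For `variable = "signal"`: `"mean"` or `"integrated"`.
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return A list of class `"group_comparison"` with `statistic` (t),
#'   `p.value`, `df`, and the two group means.
#' @export
compare_groups <- function(a, b, variable = c("area", "signal"),
                           alternative = c("greater", "less"),
                           statistic = c("mean", "integrated"),
                           welch = FALSE) {
  variable <- match.arg(variable)
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  pull <- function(df) {
    if (variable == "area") return(as.numeric(df$area_px))
    v <- if (statistic == "mean") df$perinuclear_mean
         else df$perinuclear_integrated
    v[df$ring_pixels == 0L] <- NA_real_
    v[!is.na(v)]
  }
  x <- pull(a); y <- pull(b)
  if (length(x) < 2L || length(y) < 2L)
    stop("contract error: each group needs at least 2 cells with a defined ",
         variable)
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = !welch)
  structure(list(statistic = unname(tt$statistic), p.value = tt$p.value,
                 df = unname(tt$parameter), mean_a = mean(x),
                 mean_b = mean(y), n_a = length(x), n_b = length(y),
                 variable = variable, alternative = alternative,
                 welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-tailed %s t test on %s (a %s b)\n",
              if (x$welch) "Welch" else "Student's", x$variable,
              x$alternative))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g\n", x$statistic, x$df,
              x$p.value))
  cat(sprintf("  mean a = %.4f (n = %d), mean b = %.4f (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}
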