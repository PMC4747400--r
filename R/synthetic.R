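#' Beer-Lambert stain model for brightfield rendering
#'
#' Each stain is a unit-norm optical-density vector over (R, G, B); a pixel
#' carrying hematoxylin concentration `c_h` and DAB concentration `c_d`
#' transmits `I_c = white_level_c * 10^-(c_h * hema_od_c + c_d * dab_od_c)`
#' in channel `c`. The defaults pair with the analysis side: hematoxylin is
#' red-dominant (nuclei darkest in red), DAB blue-dominant (chromogen
#' darkest in blue).
#'
#' @param hematoxylin_od Nonnegative length-3 OD vector, largest component
#'   red; normalized to unit Euclidean norm.
#' @param dab_od Nonnegative length-3 OD vector, largest component blue;
#'   normalized to unit norm.
#' @param white_level Per-channel background transmission in (0,1\].
#' @return An object of class `"stain_model"`.
#' @export
stain_model <- function(hematoxylin_od = c(0.74, 0.60, 0.30),
                        dab_od = c(0.27, 0.57, 0.78),
                        white_level = c(0.95, 0.95, 0.95)) {
  chk <- function(v, nm, dominant) {
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0))
      stop(nm, " must be a nonnegative length-3 vector")
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop(nm, " must be nonzero")
    v <- v / nv
    if (which.max(v) != dominant)
      stop(nm, " must have its largest component in the ",
           c("red", "green", "blue")[dominant], " channel")
    v
  }
  hematoxylin_od <- chk(hematoxylin_od, "hematoxylin_od", 1L)
  dab_od <- chk(dab_od, "dab_od", 3L)
  if (length(white_level) == 1L) white_level <- rep(white_level, 3L)
  if (length(white_level) != 3L || any(white_level <= 0) ||
      any(white_level > 1))
    stop("white_level must lie in (0, 1] per channel")
  structure(list(hematoxylin_od = hematoxylin_od, dab_od = dab_od,
                 white_level = white_level),
            class = "stain_model")
}

default_nucleus_columns <- function(nuclei) {
  defaults <- list(eccentricity = 0, orientation = 0,
                   hematoxylin_conc = 1, dab_conc = 0.5,
                   ring_thickness_px = 5)
  for (nm in names(defaults))
    if (is.null(nuclei[[nm]]))
      nuclei[[nm]] <- rep(defaults[[nm]], nrow(nuclei))
  nuclei
}

#' Define a synthetic IHC scene
#'
#' A scene is an image size, a table of elliptical nuclei (center in 0-based
#' (row, col) pixel coordinates, semi-major axis `radius_px`, eccentricity,
#' orientation, per-cell hematoxylin and DAB concentrations, and the
#' thickness of the perinuclear DAB shell), a background transmission level
#' and a Gaussian noise level. Rendered by [render_scene()].
#'
#' @param image_size `c(H, W)`.
#' @param nuclei Data frame with columns `center_row`, `center_col`,
#'   `radius_px`, and optionally `eccentricity` (default 0), `orientation`
#'   (radians, default 0), `hematoxylin_conc` (default 1), `dab_conc`
#'   (default 0.5), `ring_thickness_px` (default 5).
#' @param background_level Scene-wide transmission multiplier in (0,1\].
#' @param noise_sd Standard deviation of additive Gaussian noise in
#'   transmission space (clipped to \[0,1\] after adding).
#' @param seed Integer RNG seed; makes rendering bit-reproducible.
#' @return An object of class `"synthetic_scene"`.
#' @export
synthetic_scene <- function(image_size, nuclei, background_level = 1,
                            noise_sd = 0.02, seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L))
    stop("image_size must be c(H, W) with positive entries")
  nuclei <- default_nucleus_columns(as.data.frame(nuclei))
  needed <- c("center_row", "center_col", "radius_px")
  miss <- setdiff(needed, names(nuclei))
  if (length(miss)) stop("nuclei table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(nuclei)) {
    if (any(nuclei$radius_px <= 0)) stop("radii must be positive")
    if (any(nuclei$eccentricity < 0 | nuclei$eccentricity >= 1))
      stop("eccentricity must lie in [0, 1)")
    if (any(nuclei$center_row < 0 | nuclei$center_row > image_size[1] - 1 |
            nuclei$center_col < 0 | nuclei$center_col > image_size[2] - 1))
      stop("all nucleus centers must lie inside the image bounds")
    if (any(nuclei$hematoxylin_conc < 0) || any(nuclei$dab_conc < 0))
      stop("stain concentrations must be nonnegative")
    if (any(nuclei$ring_thickness_px <= 0))
      stop("ring_thickness_px must be positive")
  }
  if (length(background_level) != 1L || background_level <= 0 ||
      background_level > 1)
    stop("background_level must lie in (0, 1]")
  if (length(noise_sd) != 1L || !is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be nonnegative")
  structure(list(image_size = image_size, nuclei = nuclei,
                 background_level = background_level,
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "synthetic_scene")
}

# Linear pixel indices inside the ellipse centered at 0-based (cr, cc) with
# semi-axes (a, b) rotated by theta; pixel-center-in-ellipse rasterization.
ellipse_pixels <- function(H, W, cr, cc, a, b, theta, grow = 0) {
  a <- a + grow; b <- b + grow
  r <- max(a, b)
  r0 <- max(1L, floor(cr - r) + 1L); r1 <- min(H, ceiling(cr + r) + 1L)
  c0 <- max(1L, floor(cc - r) + 1L); c1 <- min(W, ceiling(cc + r) + 1L)
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - 1 - cr
  dc <- cols - 1 - cc
  DR <- matrix(dr, length(rows), length(cols))
  DC <- matrix(dc, length(rows), length(cols), byrow = TRUE)
  u <- DR * cos(theta) + DC * sin(theta)
  v <- -DR * sin(theta) + DC * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sel <- which(inside, arr.ind = TRUE)
  (cols[sel[, 2]] - 1L) * H + rows[sel[, 1]]
}

#' Render a synthetic scene into an image plus ground truth
#'
#' Builds per-pixel hematoxylin and DAB concentration fields (hematoxylin
#' inside each elliptical nucleus; DAB in an annular shell of
#' `ring_thickness_px` outside it), renders each channel by Beer-Lambert
#' transmission, adds seeded Gaussian noise and clips to \[0,1\]. The ground
#' truth carries the exact rasterized label mask, per-nucleus pixel areas
#' and concentrations; nuclei whose rasterizations overlap are allowed but
#' flagged.
#'
#' @param scene A [synthetic_scene()].
#' @param stains A [stain_model()].
#' @return A list with `image` (an [rgb_image()]) and `truth` (list:
#'   `labels` integer mask in which later nuclei overwrite earlier on
#'   overlap, and `nuclei`, a per-nucleus data frame with `label`,
#'   `center_row`, `center_col`, `radius_px`, `area_px`,
#'   `hematoxylin_conc`, `dab_conc`, `overlap`).
#' @export
render_scene <- function(scene, stains = stain_model()) {
  if (!inherits(scene, "synthetic_scene")) stop("expected a synthetic_scene")
  if (!inherits(stains, "stain_model")) stop("expected a stain_model")
  H <- scene$image_size[1]; W <- scene$image_size[2]
  nuc <- scene$nuclei
  n <- nrow(nuc)
  ch <- matrix(0, H, W)
  cd <- matrix(0, H, W)
  labels <- matrix(0L, H, W)
  area_px <- integer(n)
  overlap <- logical(n)
  if (n) {
    for (i in seq_len(n)) {
      a <- nuc$radius_px[i]
      b <- a * sqrt(1 - nuc$eccentricity[i]^2)
      th <- nuc$orientation[i]
      inside <- ellipse_pixels(H, W, nuc$center_row[i], nuc$center_col[i],
                               a, b, th)
      area_px[i] <- length(inside)
      hit <- labels[inside]
      if (any(hit > 0L)) {
        overlap[i] <- TRUE
        overlap[unique(hit[hit > 0L])] <- TRUE
      }
      labels[inside] <- i
      ch[inside] <- ch[inside] + nuc$hematoxylin_conc[i]
      outer <- ellipse_pixels(H, W, nuc$center_row[i], nuc$center_col[i],
                              a, b, th, grow = nuc$ring_thickness_px[i])
      shell <- setdiff(outer, inside)
      cd[shell] <- cd[shell] + nuc$dab_conc[i]
    }
  }
  px <- array(0, dim = c(H, W, 3L))
  white <- scene$background_level * stains$white_level
  for (c3 in 1:3) {
    od <- ch * stains$hematoxylin_od[c3] + cd * stains$dab_od[c3]
    px[, , c3] <- white[c3] * 10^(-od)
  }
  if (scene$noise_sd > 0) {
    noise <- with_seed(scene$seed,
                       array(stats::rnorm(H * W * 3L, sd = scene$noise_sd),
                             dim = c(H, W, 3L)))
    px <- px + noise
  }
  px <- pmin(pmax(px, 0), 1)
  truth_tab <- data.frame(label = seq_len(n),
                          center_row = nuc$center_row,
                          center_col = nuc$center_col,
                          radius_px = nuc$radius_px,
                          eccentricity = nuc$eccentricity,
                          orientation = nuc$orientation,
                          area_px = area_px,
                          hematoxylin_conc = nuc$hematoxylin_conc,
                          dab_conc = nuc$dab_conc,
                          overlap = overlap)
  list(image = rgb_image(px, dtype_scale = 1),
       truth = list(labels = labels, nuclei = truth_tab))
}

#' Random scene of well-separated elliptical nuclei
#'
#' Nucleus centers are placed by rejection sampling under a minimum
#' center-to-center distance (by default large enough that nuclei and their
#' DAB shells cannot touch; pass a small `min_spacing` to exercise watershed
#' splitting of abutting nuclei). Radii, eccentricities and stain
#' concentrations are drawn uniformly from the given ranges; per-cell DAB
#' concentrations are an evenly spaced grid over `dab_range`, randomly
#' permuted, so intensity-recovery tests see the full dynamic range.
#'
#' @param n_nuclei Number of nuclei.
#' @param image_size `c(H, W)` (default 1024 x 1024).
#' @param radius_range Semi-major axis range in px (default 10-16).
#' @param eccentricity_range Default 0-0.3.
#' @param hematoxylin_range Per-cell hematoxylin concentration range.
#' @param dab_range Per-cell DAB concentration range.
#' @param ring_thickness_px DAB shell thickness (default 5).
#' @param min_spacing Minimum center distance; default
#'   `2 * max(radius_range) + 2 * ring_thickness_px + 4`.
#' @param margin Minimum center distance from the image border; default
#'   `max(radius_range) + ring_thickness_px + 2` keeps whole cells inside.
#' @param background_level,noise_sd,seed Passed to [synthetic_scene()].
#' @return A [synthetic_scene()].
#' @export
random_scene <- function(n_nuclei = 100L, image_size = c(1024L, 1024L),
                         radius_range = c(10, 16),
                         eccentricity_range = c(0, 0.3),
                         hematoxylin_range = c(0.7, 1),
                         dab_range = c(0.15, 0.6),
                         ring_thickness_px = 5,
                         min_spacing = NULL, margin = NULL,
                         background_level = 1, noise_sd = 0.02, seed = 1L) {
  if (n_nuclei < 1L) stop("n_nuclei must be >= 1")
  if (is.null(min_spacing))
    min_spacing <- 2 * max(radius_range) + 2 * ring_thickness_px + 4
  if (is.null(margin))
    margin <- max(radius_range) + ring_thickness_px + 2
  H <- image_size[1]; W <- image_size[2]
  if (H - 2 * margin <= 0 || W - 2 * margin <= 0)
    stop("image_size too small for the requested radii")
  nuc <- with_seed(seed, {
    centers <- matrix(NA_real_, n_nuclei, 2)
    placed <- 0L
    tries <- 0L
    max_tries <- 20000L * n_nuclei
    while (placed < n_nuclei && tries < max_tries) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, margin, H - 1 - margin),
                stats::runif(1, margin, W - 1 - margin))
      if (placed == 0L ||
          min((centers[seq_len(placed), 1] - cand[1])^2 +
              (centers[seq_len(placed), 2] - cand[2])^2) >= min_spacing^2) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    if (placed < n_nuclei)
      stop("could not place ", n_nuclei, " nuclei with min_spacing ",
           min_spacing, " in a ", H, " x ", W, " image")
    data.frame(
      center_row = centers[, 1], center_col = centers[, 2],
      radius_px = stats::runif(n_nuclei, radius_range[1], radius_range[2]),
      eccentricity = stats::runif(n_nuclei, eccentricity_range[1],
                                  eccentricity_range[2]),
      orientation = stats::runif(n_nuclei, 0, pi),
      hematoxylin_conc = stats::runif(n_nuclei, hematoxylin_range[1],
                                      hematoxylin_range[2]),
      dab_conc = sample(seq(dab_range[1], dab_range[2],
                            length.out = n_nuclei)),
      ring_thickness_px = ring_thickness_px)
  })
  synthetic_scene(image_size, nuc, background_level = background_level,
                  noise_sd = noise_sd, seed = seed)
}

#' Parental / hyperploid scene pair
#'
#' Two scenes with identical layout (same seeded centers, eccentricities,
#' orientations and hematoxylin concentrations); in the "hyperploid" scene
#' every nuclear area is scaled by `ploidy_ratio` (radii by its square root,
#' so the pre-rasterization area ratio is exact) and every perinuclear DAB
#' concentration by `signal_ratio`, emulating a population with doubled DNA
#' content, enlarged nuclei and elevated perinuclear ER-stress signal.
#'
#' @param n_cells Nuclei per scene.
#' @param ploidy_ratio Area scale factor of the hyperploid population
#'   (default 2, a genome doubling).
#' @param signal_ratio DAB concentration scale factor (default 2).
#' @param seed Integer seed; the pair is fully reproducible.
#' @param image_size Default 1024 x 1024, sized for 100 well-separated
#'   hyperploid nuclei.
#' @param radius_range Parental semi-major axis range (default 10-13 px so
#'   hyperploid radii stay below 19 px).
#' @param noise_sd Rendering noise (default 0.02).
#' @return List with elements `parental` and `hyperploid`, both
#'   [synthetic_scene()] objects.
#' @export
make_population_pair <- function(n_cells, ploidy_ratio = 2,
                                 signal_ratio = 2, seed = 1L,
                                 image_size = c(1024L, 1024L),
                                 radius_range = c(10, 13),
                                 noise_sd = 0.02) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (!is.finite(ploidy_ratio) || ploidy_ratio <= 0)
    stop("ploidy_ratio must be positive")
  if (!is.finite(signal_ratio) || signal_ratio <= 0)
    stop("signal_ratio must be positive")
  scale <- sqrt(ploidy_ratio)
  ring <- 5
  # spacing and border margin sized for the larger population so both
  # layouts stay valid (no touching, no border-truncated hyperploid cells)
  spacing <- 2 * max(radius_range) * max(1, scale) + 2 * ring + 4
  margin <- max(radius_range) * max(1, scale) + ring + 2
  parental <- random_scene(n_cells, image_size = image_size,
                           radius_range = radius_range,
                           ring_thickness_px = ring,
                           min_spacing = spacing, margin = margin,
                           noise_sd = noise_sd, seed = seed)
  nuc <- parental$nuclei
  nuc$radius_px <- nuc$radius_px * scale
  nuc$dab_conc <- nuc$dab_conc * signal_ratio
  hyperploid <- synthetic_scene(parental$image_size, nuc,
                                background_level = parental$background_level,
                                noise_sd = noise_sd, seed = seed)
  list(parental = parental, hyperploid = hyperploid)
}

#' Match predicted nuclei to ground truth by intersection over union
#'
#' Greedy one-to-one matching: candidate (truth, predicted) pairs are every
#' overlapping label pair; pairs are accepted in decreasing IoU order,
#' skipping any truth or predicted label already matched.
#'
#' @param truth Ground-truth label matrix.
#' @param predicted Predicted label matrix, same shape.
#' @param iou_min Minimum IoU for a match (default 0.7).
#' @return Data frame with `truth_label`, `pred_label`, `iou`.
#' @export
match_labels <- function(truth, predicted, iou_min = 0.7) {
  if (!identical(dim(truth), dim(predicted)))
    stop("label masks must share shape")
  empty <- data.frame(truth_label = integer(0), pred_label = integer(0),
                      iou = numeric(0))
  both <- truth > 0L & predicted > 0L
  if (!any(both)) return(empty)
  ta <- tabulate(truth[truth > 0L])
  pa <- tabulate(predicted[predicted > 0L])
  ov <- table(truth[both], predicted[both])
  pairs <- as.data.frame(ov, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$Freq > 0, ]
  tl <- as.integer(pairs[[1]]); pl <- as.integer(pairs[[2]])
  inter <- pairs$Freq
  iou <- inter / (ta[tl] + pa[pl] - inter)
  keep <- iou >= iou_min
  tl <- tl[keep]; pl <- pl[keep]; iou <- iou[keep]
  ord <- order(-iou)
  used_t <- logical(max(truth)); used_p <- logical(max(predicted))
  res <- empty
  for (i in ord) {
    if (used_t[tl[i]] || used_p[pl[i]]) next
    used_t[tl[i]] <- TRUE; used_p[pl[i]] <- TRUE
    res <- rbind(res, data.frame(truth_label = tl[i], pred_label = pl[i],
                                 iou = iou[i]))
  }
  res[order(res$truth_label), , drop = FALSE]
}
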