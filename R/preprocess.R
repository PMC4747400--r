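#' Extract the red and blue component planes
#'
#' Hematoxylin (a blue dye) absorbs red light most strongly, so nuclei are
#' dark in the red plane; DAB (a brown chromogen) absorbs blue most
#' strongly, so chromogen is dark in the blue plane. The green plane is
#' discarded.
#'
#' @param image An [rgb_image()].
#' @return A list with matrices `red` and `blue`, values in \[0,1\].
#' @export
extract_channels <- function(image) {
  if (!inherits(image, "rgb_image")) stop("expected an rgb_image")
  d <- dim(image$pixels)
  red <- image$pixels[, , 1]; dim(red) <- d[1:2]
  blue <- image$pixels[, , 3]; dim(blue) <- d[1:2]
  list(red = red, blue = blue)
}

#' Log enhancement of a transmission channel
#'
#' Elementwise `L(x) = log(1 + k*x) / log(1 + k)`: the standard
#' display-enhancement log, strictly increasing on \[0,1\] with `L(0) = 0`
#' and `L(1) = 1`. It expands contrast in the dark (strongly absorbing)
#' range where stained structures live.
#'
#' @param channel Numeric vector/matrix with values in \[0,1\].
#' @param k Positive enhancement constant (default 255).
#' @return Enhanced values, same shape, in \[0,1\].
#' @export
log_enhance <- function(channel, k = 255) {
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a positive number")
  rng <- range(channel)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    stop("channel values must lie in [0, 1]")
  log1p(k * channel) / log1p(k)
}

#' @rdname log_enhance
#' @param enhanced Values previously produced by `log_enhance`.
#' @export
log_enhance_inverse <- function(enhanced, k = 255) {
  if (length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a positive number")
  expm1(enhanced * log1p(k)) / k
}

#' Build nuclear and signal absorbance-proxy maps
#'
#' First stage of the pipeline: extracts the red and blue planes,
#' log-enhances each (`k = config$log_constant_k`), and inverts them so that
#' absorbing (stained) pixels score high: `nuclear_map = 1 - L(red)` targets
#' hematoxylin-stained nuclei, `signal_map = 1 - L(blue)` targets DAB
#' chromogen. The bounded inversion `1 - L(x)` is used rather than optical
#' density `-log(x)`: it is monotone-equivalent for thresholding and has no
#' singularity at saturated dark pixels.
#'
#' @param image An [rgb_image()].
#' @param config An [analysis_config()].
#' @return An object of class `"channel_maps"`: list of matrices `red`,
#'   `blue`, `red_enhanced`, `blue_enhanced`, `nuclear_map`, `signal_map`,
#'   all in \[0,1\] and of the image's shape.
#' @export
build_maps <- function(image, config = analysis_config()) {
  ch <- extract_channels(image)
  k <- config$log_constant_k
  red_enhanced <- log_enhance(ch$red, k)
  blue_enhanced <- log_enhance(ch$blue, k)
  structure(list(red = ch$red,
                 blue = ch$blue,
                 red_enhanced = red_enhanced,
                 blue_enhanced = blue_enhanced,
                 nuclear_map = 1 - red_enhanced,
                 signal_map = 1 - blue_enhanced),
            class = "channel_maps")
}

#' @export
print.channel_maps <- function(x, ...) {
  cat(sprintf("Channel maps: %d x %d px; nuclear_map in [%.3f, %.3f], ",
              nrow(x$nuclear_map), ncol(x$nuclear_map),
              min(x$nuclear_map), max(x$nuclear_map)))
  cat(sprintf("signal_map in [%.3f, %.3f]\n",
              min(x$signal_map), max(x$signal_map)))
  invisible(x)
}
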