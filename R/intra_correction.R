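# Intra-channel background correction with alternating sequential filters.
#
# The raw channel is modeled as specific signal plus a smooth non-specific
# background (autofluorescence modulated by illumination and photobleaching,
# plus occasional large-scale artifacts such as tissue folds). Under the
# standing assumptions that (i) specific signal is brighter than background
# and (ii) cellular objects live at spatial scales within
# [sigma_min, sigma_max], the background is estimated by an alternating
# sequence of grayscale openings and closings with disk structuring elements
# whose radii double from sigma_min up to sigma_max. Openings remove bright
# structures up to the current scale (so they are *retained* in the
# corrected image); closings remove dark speckle.

#' ASF radius schedule
#'
#' Doubling schedule from `sigma_min` to `sigma_max` (inclusive): e.g.
#' `sigma_min = 2, sigma_max = 8` gives radii 2, 4, 8. If `sigma_max` is not
#' a power-of-two multiple of `sigma_min` it is appended as the final radius.
#'
#' @param sigma_min,sigma_max minimum / maximum object radii in pixels.
#' @return integer vector of disk radii.
#' @export
asf_schedule <- function(sigma_min, sigma_max) {
  if (sigma_min >= sigma_max) stop("sigma_min must be < sigma_max")
  r <- sigma_min
  out <- integer(0)
  while (r < sigma_max) {
    out <- c(out, r)
    r <- r * 2
  }
  c(out, sigma_max)
}

#' Estimate the non-specific background of a channel
#'
#' Applies the alternating sequential filter (opening-then-closing per scale,
#' scales increasing on a doubling schedule) and returns the smooth
#' background estimate. Structures whose minimal dimension is below
#' `2 * sigma_max` are excluded from the background (hence preserved by
#' subtraction); larger-scale artifacts such as folds remain in the
#' background and are removed.
#'
#' @param image a [channel_image()] or matrix.
#' @param sigma_min,sigma_max minimum / maximum object radii in pixels
#'   (radii, not diameters).
#' @return background raster in the same container type as the input.
#' @export
asf_background <- function(image, sigma_min = 2L, sigma_max = 16L) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_matrix(image)
  if (sigma_max > min(dim(px)) / 2)
    stop("sigma_max exceeds half the smallest image dimension")
  # grayscale morphology operates on the [0, 1] scale
  scale <- max(px, uint16_max)
  bg <- px / scale
  for (r in asf_schedule(sigma_min, sigma_max)) {
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    bg <- as_matrix(EBImage::closing(EBImage::opening(bg, brush), brush))
  }
  bg <- bg * scale
  if (inherits(image, "channel_image")) set_pixels(image, bg) else bg
}

#' Subtract an estimated background from a channel
#'
#' The corrected signal is `max(image - background, 0)` (fluorescence is
#' non-negative). Where no clipping occurs, `corrected + background`
#' reproduces the input exactly.
#'
#' @param image,background [channel_image()]s or matrices of equal geometry.
#' @return `list(corrected, background)` of `channel_image`s.
#' @export
subtract_background <- function(image, background) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_matrix(image)
  bg <- if (inherits(background, "channel_image")) background$pixels else as_matrix(background)
  if (!identical(dim(px), dim(bg)))
    stop("subtract_background: geometry mismatch")
  corr <- pmax(px - bg, 0)
  img_out <- if (inherits(image, "channel_image")) set_pixels(image, corr)
    else channel_image(corr)
  bg_out <- if (inherits(image, "channel_image")) set_pixels(image, bg)
    else channel_image(bg)
  list(corrected = img_out, background = bg_out)
}

#' One-call intra-channel correction
#' @inheritParams asf_background
#' @return `list(corrected, background)`.
#' @export
correct_channel <- function(image, sigma_min = 2L, sigma_max = 16L) {
  subtract_background(image, asf_background(image, sigma_min, sigma_max))
}

#' Clip debris brighter than any pixel in a clean reference ROI
#'
#' The ROI is assumed debris-free and to contain the brightest true signal;
#' any pixel brighter than the ROI maximum is clipped to that maximum,
#' removing random bright specks and sediment.
#'
#' @param image [channel_image()] or matrix.
#' @param roi half-open rectangle `c(r0, c0, r1, c1)`, 0-based.
#' @return clipped image, same container type.
#' @export
clip_debris <- function(image, roi) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_matrix(image)
  if (!rect_valid(roi, dim(px))) stop("clip_debris: empty or invalid roi")
  m <- max(crop_rect(px, roi))
  px[px > m] <- m
  if (inherits(image, "channel_image")) set_pixels(image, px) else px
}
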