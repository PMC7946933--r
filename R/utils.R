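# Internal helpers shared across the pipeline.
#
# Coordinate conventions (used everywhere):
#  * pixels are addressed 0-based as (row, col), pixel-centered;
#  * boxes are half-open rectangles [r0, r1) x [c0, c1) stored as
#    c(r0, c0, r1, c1);
#  * R matrices are 1-based, so matrix index = coordinate + 1.

#' @importFrom stats density rnorm runif sd quantile setNames coef lm.fit
#' @importFrom utils head read.delim write.csv read.csv
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- boxes ------------------------------------------------------------------

box_area <- function(b) {
  pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
}

as_box_matrix <- function(b) {
  if (is.null(dim(b))) matrix(b, ncol = 4, byrow = TRUE) else as.matrix(b)
}

# IOU of one box against a matrix of boxes (half-open arithmetic).
box_iou <- function(b, boxes) {
  boxes <- as_box_matrix(boxes)
  ir0 <- pmax(b[1], boxes[, 1]); ic0 <- pmax(b[2], boxes[, 2])
  ir1 <- pmin(b[3], boxes[, 3]); ic1 <- pmin(b[4], boxes[, 4])
  inter <- pmax(0, ir1 - ir0) * pmax(0, ic1 - ic0)
  a1 <- (b[3] - b[1]) * (b[4] - b[2])
  a2 <- (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
  inter / (a1 + a2 - inter)
}

# Greedy non-maximum suppression; returns indices of surviving boxes.
nms_boxes <- function(boxes, scores, iou_thr) {
  boxes <- as_box_matrix(boxes)
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(-scores, seq_len(n))
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & !keep)
    if (length(rest)) {
      iou <- box_iou(boxes[i, ], boxes[rest, , drop = FALSE])
      alive[rest[iou > iou_thr]] <- FALSE
    }
  }
  which(keep)
}

# -- thresholds -------------------------------------------------------------

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Valley-between-modes threshold for bimodal data; NA when no clear valley.
valley_threshold <- function(x, min_depth = 0.15) {
  x <- x[is.finite(x)]
  if (length(x) < 10 || diff(range(x)) == 0) return(NA_real_)
  d <- density(x, n = 512)
  y <- d$y
  is_max <- y > c(-Inf, head(y, -1)) & y >= c(tail(y, -1), Inf)
  peaks <- which(is_max)
  if (length(peaks) < 2) return(NA_real_)
  peaks <- peaks[order(-y[peaks])][1:2]
  lo <- min(peaks); hi <- max(peaks)
  valley <- lo + which.min(y[lo:hi]) - 1L
  depth <- 1 - y[valley] / min(y[lo], y[hi])
  if (!is.finite(depth) || depth < min_depth) return(NA_real_)
  d$x[valley]
}

# Bimodal threshold: valley if detectable, else Otsu. Attribute "method"
# records which estimator produced the value.
bimodal_threshold <- function(x) {
  thr <- valley_threshold(x)
  method <- "valley"
  if (is.na(thr)) {
    thr <- otsu_threshold(x)
    method <- "otsu"
  }
  structure(thr, method = method)
}

# -- affine geometry --------------------------------------------------------

# 2x3 affine matrix [A | t] acting on 0-based (row, col) coordinates.
affine_identity <- function() cbind(diag(2), c(0, 0))

# Build an affine around a center point: rotation (deg), scale, translation.
affine_about_center <- function(center_rc, rotation_deg = 0, scale = 1,
                                translation = c(0, 0)) {
  th <- rotation_deg * pi / 180
  A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- center_rc - A %*% center_rc + translation
  cbind(A, t)
}

affine_apply <- function(M, pts) {
  # pts: n x 2 matrix of (row, col)
  pts <- matrix(pts, ncol = 2)
  t(M[, 1:2] %*% t(pts)) + matrix(M[, 3], nrow(pts), 2, byrow = TRUE)
}

affine_invert <- function(M) {
  A <- M[, 1:2]
  d <- det(A)
  if (abs(d) < 1e-6) stop("affine transform is singular")
  Ai <- solve(A)
  cbind(Ai, -Ai %*% M[, 3])
}

affine_compose <- function(M2, M1) {
  # returns transform doing M1 first, then M2
  cbind(M2[, 1:2] %*% M1[, 1:2], M2[, 1:2] %*% M1[, 3] + M2[, 3])
}

# Inverse-mapped bilinear warp of a matrix. M maps input coords to output
# coords (0-based row,col); out-of-field pixels are 0.
warp_affine <- function(img, M, dim_out = dim(img)) {
  Mi <- affine_invert(M)
  nr <- dim_out[1]; nc <- dim_out[2]
  rr <- rep(seq_len(nr) - 1, times = nc)
  cc <- rep(seq_len(nc) - 1, each = nr)
  src_r <- Mi[1, 1] * rr + Mi[1, 2] * cc + Mi[1, 3]
  src_c <- Mi[2, 1] * rr + Mi[2, 2] * cc + Mi[2, 3]
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  H <- nrow(img); W <- ncol(img)
  # gather with zero padding
  gather <- function(r, c) {
    ok <- r >= 0 & r <= H - 1 & c >= 0 & c <= W - 1
    v <- numeric(length(r))
    v[ok] <- img[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  v00 <- gather(r0, c0); v01 <- gather(r0, c0 + 1)
  v10 <- gather(r0 + 1, c0); v11 <- gather(r0 + 1, c0 + 1)
  out <- (1 - fr) * (1 - fc) * v00 + (1 - fr) * fc * v01 +
    fr * (1 - fc) * v10 + fr * fc * v11
  matrix(out, nr, nc)
}

# -- misc raster helpers ----------------------------------------------------

# Shift a matrix by (dr, dc), zero-filling; used by vectorized filters.
shift_matrix <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  src_r <- max(1, 1 - dr):min(H, H - dr)
  src_c <- max(1, 1 - dc):min(W, W - dc)
  if (length(src_r) && length(src_c))
    out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

clip01 <- function(x) pmin(1, pmax(0, x))

# dim-preserving clamp (pmax/pmin drop dims when a scalar comes first)
clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

uint16_max <- 65535

as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}

rect_valid <- function(roi, dims) {
  length(roi) == 4 && roi[1] >= 0 && roi[2] >= 0 &&
    roi[3] <= dims[1] && roi[4] <= dims[2] && roi[3] > roi[1] && roi[4] > roi[2]
}

crop_rect <- function(img, roi) {
  img[(roi[1] + 1):roi[3], (roi[2] + 1):roi[4], drop = FALSE]
}
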