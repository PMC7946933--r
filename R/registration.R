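# Inter-round registration.
#
# Each staining round is aligned to the reference round with a single affine
# transform estimated from the DAPI channel: oriented FAST-9 corners with
# steered 256-bit BRIEF binary descriptors are extracted per window of a
# grid, matched by mutual nearest neighbors under Hamming distance, and the
# transform is estimated by RANSAC over 3-point minimal samples followed by a
# least-squares refit on the inlier consensus set. The tissue is minimally
# deformed between rounds, so an affine model is adequate; sub-pixel accuracy
# comes from the final least-squares refit.

# FAST circle of radius 3 (16 offsets, circular order), (row, col)
fast_circle <- cbind(
  c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3),
  c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1))

# Fixed BRIEF sampling pattern: 256 pairs of offsets within a 49 px patch.
# The footprint is wide relative to a single nucleus so each descriptor
# captures the local constellation of nuclei (individual nuclei are
# featureless blobs and would be ambiguous on their own).
brief_pattern <- local({
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(987654L)
  p <- matrix(pmax(-24, pmin(24, round(rnorm(256 * 4, 0, 8)))), 256, 4)
  if (has_seed) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  p  # columns: a_row, a_col, b_row, b_col
})

#' Detect oriented keypoints with binary descriptors
#'
#' FAST-9 corners (segment test on a radius-3 circle of 16 pixels, at least 9
#' contiguous brighter or darker than the center) with intensity-centroid
#' orientation and steered 256-bit BRIEF descriptors, extracted independently
#' per window of a `grid[1] x grid[2]` partition and capped at
#' `n_per_window` strongest corners per window. A constant image yields an
#' empty set.
#'
#' @param image [channel_image()] or matrix (typically the round's DAPI).
#' @param grid windows along (rows, cols).
#' @param n_per_window keypoint cap per window.
#' @param threshold_frac FAST intensity threshold as a fraction of the image
#'   dynamic range.
#' @return `list(positions, descriptors, window_id, scores)`; positions are
#'   0-based `(row, col)`, descriptors an `n x 256` logical matrix.
#' @export
detect_keypoints <- function(image, grid = c(8L, 8L), n_per_window = 500L,
                             threshold_frac = 0.06) {
  px <- if (inherits(image, "channel_image")) image$pixels else as_matrix(image)
  H <- nrow(px); W <- ncol(px)
  empty <- list(positions = matrix(0, 0, 2),
                descriptors = matrix(FALSE, 0, 256),
                window_id = integer(0), scores = numeric(0))
  rng <- range(px)
  if (diff(rng) == 0) return(empty)
  sm <- as_matrix(EBImage::gblur(px, 1.2))
  t <- threshold_frac * diff(range(sm))
  shifted <- lapply(seq_len(16), function(k)
    shift_matrix(sm, -fast_circle[k, 1], -fast_circle[k, 2]))
  bright <- lapply(shifted, function(s) s > sm + t)
  dark <- lapply(shifted, function(s) s < sm - t)
  arc9 <- function(masks) {
    acc <- matrix(FALSE, H, W)
    for (s in 1:16) {
      a <- masks[[s]]
      for (j in 1:8) a <- a & masks[[(s + j - 1) %% 16 + 1]]
      acc <- acc | a
    }
    acc
  }
  corner <- arc9(bright) | arc9(dark)
  margin <- 35L
  corner[c(seq_len(margin), H - seq_len(margin) + 1L), ] <- FALSE
  corner[, c(seq_len(margin), W - seq_len(margin) + 1L)] <- FALSE
  if (!any(corner)) return(empty)
  score <- Reduce(`+`, lapply(shifted, function(s) pmax(abs(s - sm) - t, 0)))
  # 3x3 non-maximum suppression
  is_max <- matrix(TRUE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & score >= shift_matrix(score, dr, dc, fill = -Inf)
  }
  keep <- which(corner & is_max, arr.ind = TRUE)
  scores <- score[keep]
  # window assignment + per-window cap
  wr <- pmin(grid[1], 1L + (keep[, 1] - 1L) %/% ceiling(H / grid[1]))
  wc <- pmin(grid[2], 1L + (keep[, 2] - 1L) %/% ceiling(W / grid[2]))
  win <- (wr - 1L) * grid[2] + wc
  ord <- order(win, -scores)
  keep <- keep[ord, , drop = FALSE]; scores <- scores[ord]; win <- win[ord]
  sel <- unlist(lapply(split(seq_along(win), win),
                       function(ix) head(ix, n_per_window)), use.names = FALSE)
  keep <- keep[sel, , drop = FALSE]; scores <- scores[sel]; win <- win[sel]
  n <- nrow(keep)
  # orientation by intensity centroid over a radius-12 disk
  disk <- which(matrix(TRUE, 25, 25), arr.ind = TRUE) - 13L
  disk <- disk[rowSums(disk^2) <= 144, , drop = FALSE]
  gat <- function(dr, dc) {
    r <- pmin(H, pmax(1, keep[, 1] + dr)); c <- pmin(W, pmax(1, keep[, 2] + dc))
    sm[cbind(r, c)]
  }
  m01 <- m10 <- numeric(n)
  for (i in seq_len(nrow(disk))) {
    v <- gat(disk[i, 1], disk[i, 2])
    m01 <- m01 + disk[i, 1] * v   # row moment
    m10 <- m10 + disk[i, 2] * v   # col moment
  }
  theta <- atan2(m01, m10)
  ct <- cos(theta); st <- sin(theta)
  desc <- matrix(FALSE, n, 256)
  for (j in seq_len(256)) {
    p <- brief_pattern[j, ]
    # rotate offsets by theta (col = x, row = y)
    ar <- round(st * p[2] + ct * p[1]); ac <- round(ct * p[2] - st * p[1])
    br <- round(st * p[4] + ct * p[3]); bc <- round(ct * p[4] - st * p[3])
    desc[, j] <- gat(ar, ac) < gat(br, bc)
  }
  list(positions = unname(keep) - 1, descriptors = desc,
       window_id = as.integer(win), scores = scores)
}

#' Match binary descriptors by mutual nearest neighbors (Hamming)
#'
#' Pairs are kept when each is the other's nearest neighbor in Hamming
#' distance and the best/second-best distance ratio is at most `max_ratio`.
#' Either set empty yields an empty match list.
#'
#' @param a,b keypoint sets from [detect_keypoints()].
#' @param max_ratio Lowe-style ratio-test cutoff (set to 1 to disable).
#' @return integer matrix with columns `idx_a`, `idx_b`.
#' @export
match_keypoints <- function(a, b, max_ratio = 0.9) {
  if (nrow(a$descriptors) == 0 || nrow(b$descriptors) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("idx_a", "idx_b"))))
  A <- a$descriptors * 1; B <- b$descriptors * 1
  D <- A %*% (1 - t(B)) + (1 - A) %*% t(B)   # Hamming distances
  best_b <- max.col(-D, ties.method = "first")
  best_a <- max.col(-t(D), ties.method = "first")
  i <- seq_len(nrow(D))
  mutual <- best_a[best_b[i]] == i
  if (ncol(D) >= 2 && max_ratio < 1) {
    d1 <- D[cbind(i, best_b)]
    D2 <- D; D2[cbind(i, best_b)] <- Inf
    d2 <- apply(D2, 1, min)
    mutual <- mutual & (d1 <= max_ratio * d2)
  }
  out <- cbind(idx_a = i[mutual], idx_b = best_b[mutual])
  out
}

#' Robust affine estimation with RANSAC
#'
#' Samples 3-point minimal sets, fits the exact affine, scores inliers by
#' reprojection residual, and refits by least squares on the best consensus
#' set (twice, re-collecting inliers in between). Deterministic given `seed`.
#'
#' @param matches index pairs from [match_keypoints()].
#' @param positions_a,positions_b 0-based `(row, col)` keypoint positions;
#'   the returned transform maps `a` coordinates into `b` coordinates.
#' @param inlier_tol_px residual below which a match counts as an inlier.
#' @param max_iter RANSAC iterations.
#' @param min_inliers minimum consensus size; fewer is a failure.
#' @param seed RNG seed.
#' @return `list(transform, inliers)`; errors with class
#'   `"registration_failed"` (carrying diagnostics) when no consensus exists.
#' @export
estimate_affine <- function(matches, positions_a, positions_b,
                            inlier_tol_px = 2, max_iter = 2000L,
                            min_inliers = 20L, seed = 1L) {
  fail <- function(msg, diag = list()) {
    cnd <- structure(class = c("registration_failed", "error", "condition"),
                     list(message = paste0("registration failed: ", msg),
                          call = sys.call(-1), diagnostics = diag))
    stop(cnd)
  }
  n <- nrow(matches)
  if (is.null(n) || n < 3) fail("fewer than 3 matches", list(n_matches = n %||% 0))
  pa <- matrix(positions_a[matches[, 1], ], ncol = 2)
  pb <- matrix(positions_b[matches[, 2], ], ncol = 2)
  Xa <- cbind(pa, 1)
  fit_ls <- function(idx) {
    M <- tryCatch(qr.solve(Xa[idx, , drop = FALSE], pb[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(M)) return(NULL)
    t(M)  # 2x3 acting on (row, col, 1)
  }
  resid <- function(M) sqrt(rowSums((Xa %*% t(M) - pb)^2))
  best_n <- -1L; best_in <- NULL
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      s <- sample.int(n, 3L)
      d <- det(cbind(pa[s[2:3], , drop = FALSE] -
                       matrix(pa[s[1], ], 2, 2, byrow = TRUE)))
      if (abs(d) < 1e-6) next
      M <- fit_ls(s)
      if (is.null(M)) next
      inl <- resid(M) < inlier_tol_px
      if (sum(inl) > best_n) { best_n <- sum(inl); best_in <- inl }
    }
  })
  if (best_n < max(3L, min_inliers))
    fail(sprintf("consensus too small (%d < %d)", max(best_n, 0L), min_inliers),
         list(n_matches = n, best_consensus = max(best_n, 0L)))
  M <- fit_ls(which(best_in))
  inl <- resid(M) < inlier_tol_px
  if (sum(inl) >= 3) M <- fit_ls(which(inl))
  if (abs(det(M[, 1:2])) < 1e-6) fail("estimated transform is singular")
  list(transform = M, inliers = resid(M) < inlier_tol_px)
}

#' Register one staining round to the reference round
#'
#' Estimates a single affine transform from the moving round's DAPI channel
#' to the fixed DAPI, then applies it to every channel of the round via
#' inverse-mapped bilinear interpolation (out-of-field pixels set to 0).
#'
#' @param moving_round list of [channel_image()]s (must contain DAPI).
#' @param fixed_dapi reference-round DAPI [channel_image()].
#' @param grid,n_per_window keypoint extraction controls
#'   (see [detect_keypoints()]).
#' @param inlier_tol_px,max_iter,min_inliers,seed RANSAC controls
#'   (see [estimate_affine()]).
#' @return `list(channels, transform, n_matches, n_inliers)`.
#' @export
register_round <- function(moving_round, fixed_dapi, grid = c(8L, 8L),
                           n_per_window = 500L, inlier_tol_px = 2,
                           max_iter = 2000L, min_inliers = 20L, seed = 1L) {
  mov_dapi <- get_channel(moving_round, "DAPI")
  if (is.null(mov_dapi)) stop("moving round has no DAPI channel")
  kp_m <- detect_keypoints(mov_dapi, grid, n_per_window)
  kp_f <- detect_keypoints(fixed_dapi, grid, n_per_window)
  mt <- match_keypoints(kp_m, kp_f)
  est <- estimate_affine(mt, kp_m$positions, kp_f$positions,
                         inlier_tol_px, max_iter, min_inliers, seed)
  M <- est$transform
  dim_out <- dim(fixed_dapi$pixels)
  channels <- lapply(moving_round, function(ch)
    set_pixels(ch, warp_affine(ch$pixels, M, dim_out)))
  list(channels = channels, transform = M,
       n_matches = nrow(mt), n_inliers = sum(est$inliers))
}

#' Register a whole multi-round stack to its first round
#'
#' @param stack list of [channel_image()]s covering several rounds.
#' @param reference_round round id used as the fixed geometry.
#' @param ... passed to [register_round()].
#' @return `list(stack, transforms)` with per-round 2x3 matrices
#'   (identity for the reference round).
#' @export
register_stack <- function(stack, reference_round = 1L, ...) {
  rounds <- sort(unique(vapply(stack, function(x) x$round_id, 1L)))
  fixed_dapi <- get_channel(stack, "DAPI", reference_round)
  if (is.null(fixed_dapi)) stop("reference round has no DAPI channel")
  out <- stack
  transforms <- setNames(vector("list", length(rounds)), as.character(rounds))
  for (r in rounds) {
    idx <- which(vapply(stack, function(x) x$round_id, 1L) == r)
    if (r == reference_round) {
      transforms[[as.character(r)]] <- affine_identity()
      next
    }
    reg <- register_round(stack[idx], fixed_dapi, ...)
    out[idx] <- reg$channels
    transforms[[as.character(r)]] <- reg$transform
  }
  list(stack = out, transforms = transforms)
}

#' Serialize / read an affine transform as JSON
#' @param transform 2x3 affine matrix.
#' @param path JSON path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(matrix = transform), path, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  matrix(as.numeric(m), 2, 3)
}
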