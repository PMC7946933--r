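# Semi-supervised constrained sparse linear unmixing.
#
# After intra-channel correction, a target channel may still contain two
# kinds of inter-channel contamination: spectral bleed-through (a uniform
# fraction alpha_c' of another channel leaking through the filter band) and
# molecular cross-labeling (object-borne non-specific binding, fraction
# beta_c'' of a user-declared channel). Bleed-through donors are discovered
# automatically by a nonnegative l1-regularized least-squares fit (LASSO) of
# the target on the other channels over a user ROI; cross-labeling donors
# come from the declared set E. The joint model is then refined by
# box-constrained least squares on the active set under a budget of at most
# K active contaminant channels, and the fitted fractions are subtracted
# from the target (clipped at zero).

# Projected coordinate descent for
#   min_{0 <= a_j <= upper_j} || y - X a ||^2 + gamma * sum_j pen_j a_j
# (pen_j = 0 marks unpenalized columns, e.g. an offset term).
nnlasso_cd <- function(X, y, gamma = 0, upper = Inf, pen = 1,
                       max_iter = 500L, tol = 1e-9) {
  p <- ncol(X)
  if (p == 0L) return(numeric(0))
  upper <- rep_len(upper, p)
  pen <- rep_len(pen, p)
  a <- numeric(p)
  xtx <- colSums(X^2)
  r <- y  # residual y - X a
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xtx[j] == 0) next
      aj_old <- a[j]
      rho <- sum(X[, j] * r) + aj_old * xtx[j]
      aj <- min(upper[j], max(0, (rho - pen[j] * gamma / 2) / xtx[j]))
      if (aj != aj_old) {
        r <- r - (aj - aj_old) * X[, j]
        delta <- max(delta, abs(aj - aj_old))
      }
      a[j] <- aj
    }
    if (delta < tol) break
  }
  a
}

# NNLS/lasso fit of target on donors with an unpenalized nonnegative
# offset column absorbing the shared residual-background level.
fit_fractions <- function(X, y, gamma) {
  Xi <- cbind(1, X)
  a <- nnlasso_cd(Xi, y, gamma = gamma,
                  upper = c(Inf, rep(0.999, ncol(X))),
                  pen = c(0, rep(1, ncol(X))))
  a[-1]
}

# Deterministic subsample of up to n_max ROI pixels (evenly spaced).
sample_roi_pixels <- function(mats, roi, n_max = 1e5) {
  vecs <- lapply(mats, function(m) as.numeric(crop_rect(m, roi)))
  n <- length(vecs[[1]])
  if (n > n_max) {
    idx <- round(seq(1, n, length.out = n_max))
    vecs <- lapply(vecs, function(v) v[idx])
  }
  do.call(cbind, vecs)
}

pixels_of <- function(x) if (inherits(x, "channel_image")) x$pixels else as_matrix(x)

# Restrict a sampled pixel matrix (col 1 = target, rest = donors) to
# signal-bearing pixels, and flag donors with no detectable ROI signal.
# Residual background after intra-correction is spatially correlated across
# channels (shared autofluorescence texture), so fits over background-
# dominated pixels would attribute spurious fractions to signal-free
# channels; bleed-through is only identifiable from donor object pixels.
signal_fit_subset <- function(S, min_pixels = 200L, min_signal = 50L) {
  q999 <- apply(S, 2, quantile, 0.999, names = FALSE)
  q50 <- apply(S, 2, quantile, 0.5, names = FALSE)
  # a donor must show object-like contrast AND a signal scale comparable to
  # the stack (a channel holding only residual background is not a donor)
  informative <- q999 > 20 * (q50 + 1) & q999 > 0.05 * max(q999)
  bright <- matrix(FALSE, nrow(S), ncol(S))
  for (j in which(informative))
    bright[, j] <- S[, j] > 0.25 * q999[j]
  # fit rows are DONOR object pixels: pixels bright only in the target carry
  # its own (unexplainable) specific signal and would swamp the regression
  rows <- rowSums(bright[, -1, drop = FALSE]) > 0
  donor_ok <- informative[-1] & colSums(bright[, -1, drop = FALSE]) >= min_signal
  if (sum(rows) < min_pixels) rows <- rep(TRUE, nrow(S))
  list(rows = rows, donor_ok = donor_ok)
}

# Cross-validated gamma on ROI pixels (5-fold, log-spaced grid).
cv_gamma <- function(X, y, n_folds = 5L, grid = NULL) {
  n <- length(y)
  if (is.null(grid)) {
    gmax <- max(abs(crossprod(X, y))) * 2
    grid <- gmax * 10^seq(-5, -1, length.out = 7)
  }
  fold <- rep_len(seq_len(n_folds), n)
  errs <- sapply(grid, function(g) {
    sapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      a <- fit_fractions(X[tr, , drop = FALSE], y[tr], gamma = g)
      mean((y[!tr] - X[!tr, , drop = FALSE] %*% a)^2)
    })
  })
  mu <- colMeans(errs)
  se <- apply(errs, 2, sd) / sqrt(n_folds)
  # one-standard-error rule: strongest sparsity whose CV error is within
  # one SE of the minimum
  ok <- mu <= min(mu) + se[which.min(mu)]
  max(grid[ok])
}

#' Estimate bleed-through fractions by nonnegative LASSO
#'
#' Fits the target channel's ROI pixels on all other channels' ROI pixels
#' with a nonnegative l1-regularized least-squares model. Channels whose
#' fitted fraction exceeds the activation tolerance (1e-3) are flagged as
#' bleed-through donors. `gamma = 0` reduces to nonnegative least squares;
#' `gamma = NULL` selects gamma by 5-fold cross-validation on the ROI
#' pixels. Deterministic (pixel subsampling is evenly spaced, not random).
#'
#' @param target [channel_image()] (intra-corrected).
#' @param others list of candidate donor [channel_image()]s.
#' @param roi half-open rectangle `c(r0, c0, r1, c1)` containing background,
#'   autofluorescence and bright specific signal; at least 32 x 32 px.
#' @param gamma sparsity trade-off (`NULL` = cross-validated).
#' @param n_sample maximum number of ROI pixels used in the fit.
#' @return `list(alpha, e_bleed, gamma)`; `alpha` named by donor biomarker.
#' @export
estimate_bleedthrough <- function(target, others, roi, gamma = NULL,
                                  n_sample = 1e5) {
  tp <- pixels_of(target)
  if (!rect_valid(roi, dim(tp)) || roi[3] - roi[1] < 32 || roi[4] - roi[2] < 32)
    stop("insufficient pixels: ROI must be at least 32 x 32 px")
  mats <- c(list(tp), lapply(others, pixels_of))
  S <- sample_roi_pixels(mats, roi, n_sample)
  sub <- signal_fit_subset(S)
  y <- S[sub$rows, 1]
  X <- S[sub$rows, -1, drop = FALSE][, sub$donor_ok, drop = FALSE]
  a_fit <- if (ncol(X)) {
    if (is.null(gamma)) gamma <- cv_gamma(X, y)
    fit_fractions(X, y, gamma)
  } else numeric(0)
  a <- numeric(length(others))
  a[sub$donor_ok] <- a_fit
  nm <- vapply(others, function(o)
    if (inherits(o, "channel_image")) o$biomarker else "", "")
  names(a) <- nm
  list(alpha = a, e_bleed = a > 1e-3, gamma = gamma %||% 0)
}

#' Unmix one channel against its contaminant donors
#'
#' Jointly refines bleed-through fractions (over automatically flagged
#' donors) and cross-labeling fractions (over the user-declared set `E`) by
#' box-constrained least squares on the ROI, enforces the budget of at most
#' `K` active contaminant channels (the K largest fitted fractions are
#' retained on overflow, then refit), and subtracts the fitted mixture from
#' the target, clipping at zero. Declared cross-labeling channels are
#' excluded from the automatic bleed-through candidates.
#'
#' @param target [channel_image()] to correct.
#' @param others list of all other channels in the stack.
#' @param roi unmixing ROI (see [estimate_bleedthrough()]).
#' @param E integer or character indices into `others` declaring expected
#'   cross-labeling donors (may be empty).
#' @param K maximum number of active contaminant channels (bleed-through
#'   plus cross-labeling together); the default 3 covers both in practice.
#' @param gamma sparsity trade-off for the discovery fit (`NULL` = CV).
#' @param literal_sum_k if `TRUE`, additionally rescale the active fractions
#'   so they sum exactly to `K` (the literal equality-constraint reading;
#'   off by default, see the methods vignette).
#' @return `list(corrected, model)` where `model` has `alpha`, `beta`,
#'   `e_bleed`, `E`, `K`, `gamma`.
#' @export
unmix_channel <- function(target, others, roi, E = integer(0), K = 3L,
                          gamma = NULL, literal_sum_k = FALSE) {
  if (K == 0L && length(E) > 0)
    stop("infeasible constraints: K = 0 with nonempty declared set E")
  nm <- vapply(others, function(o)
    if (inherits(o, "channel_image")) o$biomarker else "", "")
  if (is.character(E)) E <- match(E, nm)
  E <- as.integer(E)
  auto_idx <- setdiff(seq_along(others), E)
  est <- if (length(auto_idx))
    estimate_bleedthrough(target, others[auto_idx], roi, gamma = gamma)
  else list(alpha = numeric(0), e_bleed = logical(0), gamma = gamma %||% 0)
  bleed_idx <- auto_idx[est$e_bleed]
  active <- c(bleed_idx, E)
  alpha_full <- setNames(numeric(length(others)), nm)
  beta_full <- setNames(numeric(length(others)), nm)
  if (length(active)) {
    tp <- pixels_of(target)
    refit <- function(act) {
      S <- sample_roi_pixels(c(list(tp), lapply(others[act], pixels_of)), roi)
      sub <- signal_fit_subset(S)
      a <- numeric(length(act))
      Xs <- S[sub$rows, -1, drop = FALSE][, sub$donor_ok, drop = FALSE]
      if (ncol(Xs))
        a[sub$donor_ok] <- fit_fractions(Xs, S[sub$rows, 1], gamma = 0)
      a
    }
    a <- refit(active)
    act <- active[a > 1e-3]
    a <- a[a > 1e-3]
    if (length(act) > K) {         # budget overflow: keep K largest fractions
      keep <- order(-a)[seq_len(K)]
      act <- act[keep]
      a <- refit(act)
      act <- act[a > 1e-3]
      a <- a[a > 1e-3]
    }
    if (literal_sum_k && sum(a) > 0) a <- a * (K / sum(a))
    corr <- tp
    for (i in seq_along(act)) {
      corr <- corr - a[i] * pixels_of(others[[act[i]]])
      if (act[i] %in% E) beta_full[act[i]] <- a[i] else alpha_full[act[i]] <- a[i]
    }
    corr <- pmax(corr, 0)
    out <- if (inherits(target, "channel_image")) set_pixels(target, corr)
      else channel_image(corr)
  } else {
    out <- target
  }
  model <- list(alpha = alpha_full, beta = beta_full,
                e_bleed = alpha_full > 1e-3, E = nm[E], K = K,
                gamma = est$gamma)
  list(corrected = out, model = model)
}

#' Unmix every channel of a registered, intra-corrected stack
#'
#' @param stack list of [channel_image()]s.
#' @param E_pairs list of `c(target_biomarker, source_biomarker)` pairs
#'   declaring expected cross-labeling (may be empty).
#' @param roi unmixing ROI.
#' @param K active-channel budget per target.
#' @param gamma sparsity trade-off (`NULL` = CV per channel).
#' @param exclude_biomarkers reference channels left out of unmixing (as
#'   targets and donors); nuclear counterstains are imaged in every round
#'   for registration and co-localize with every nucleated marker, so they
#'   are not bleed-through candidates.
#' @return `list(stack, models)`; models named by `"R<round>:<biomarker>"`.
#' @export
unmix_stack <- function(stack, E_pairs = list(), roi, K = 3L, gamma = NULL,
                        exclude_biomarkers = c("DAPI", "Histone")) {
  keys <- vapply(stack, function(x) paste0("R", x$round_id, ":", x$biomarker), "")
  out <- stack
  models <- setNames(vector("list", length(stack)), keys)
  excluded <- stack_biomarkers(stack) %in% exclude_biomarkers
  for (i in seq_along(stack)) {
    if (excluded[i]) next
    others <- stack[-i][!excluded[-i]]
    other_names <- vapply(others, function(o) o$biomarker, "")
    E <- unique(unlist(lapply(E_pairs, function(p)
      if (p[1] == stack[[i]]$biomarker) which(other_names == p[2]))))
    E <- as.integer(E %||% integer(0))
    res <- tryCatch(
      unmix_channel(stack[[i]], others, roi, E = E, K = K, gamma = gamma),
      error = function(e)
        stop("unmixing failed for channel '", keys[i], "': ",
             conditionMessage(e)))
    out[[i]] <- res$corrected
    models[[i]] <- res$model
  }
  list(stack = out, models = models)
}

#' Write fitted mixing models to JSON
#' @param models model list from [unmix_stack()].
#' @param path output JSON path.
#' @export
write_mixing_models <- function(models, path) {
  ser <- lapply(models, function(m) {
    if (is.null(m)) return(NULL)
    list(alpha = as.list(m$alpha), beta = as.list(m$beta),
         e_bleed = as.list(m$e_bleed), E = m$E, K = m$K, gamma = m$gamma)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
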