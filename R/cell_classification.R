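# Open-set cell typing with a capsule network.
#
# Each detected cell is assigned one of the major brain cell types (neuron,
# astrocyte, oligodendrocyte, microglia, endothelial) or "Unknown". The
# classifier is a capsule network: a learned feature layer feeds P primary
# capsules (dim 8, squashed), which are routed (dynamic routing, 3
# iterations) into K class capsules of dimension 16. The Euclidean length of
# each class vector, squashed into [0, 1], encodes the existence probability
# of that type; if every length falls below `unknown_threshold` (0.5) the
# cell is assigned to the unknown class. Training minimizes the margin loss
#   L = sum_k [ T_k max(0, m+ - |V_k|)^2
#               + lambda (1 - T_k) max(0, |V_k| - m-)^2 ]
# with m+ = 0.9, m- = 0.1, lambda = 0.5. The efficiency variant used here
# shares a single transform per (primary, class) pair across the batch
# (shared-transform primary capsules). An intensity-threshold baseline
# classifier is provided for comparison.

format_type <- function(x) {
  map <- c(neuron = "Neuron", astrocyte = "Astrocyte",
           oligodendrocyte = "Oligodendrocyte", microglia = "Microglia",
           endothelial = "Endothelial", unknown = "Unknown")
  out <- unname(map[x])
  ifelse(is.na(out), x, out)
}

#' Classifier parameters
#' @param unknown_threshold open-set cutoff on the maximum capsule length.
#' @param m_plus,m_minus,lambda margin-loss constants.
#' @param training_top_n cells per type used to build the training corpus.
#' @param patch_size square patch side (pixels) extracted around each cell.
#' @param routing_iters dynamic-routing iterations.
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(unknown_threshold = 0.5, m_plus = 0.9,
                              m_minus = 0.1, lambda = 0.5,
                              training_top_n = 5000L, patch_size = 32L,
                              routing_iters = 3L) {
  stopifnot(m_minus > 0, m_minus < m_plus, m_plus < 1,
            unknown_threshold > 0, unknown_threshold < 1)
  structure(list(unknown_threshold = unknown_threshold, m_plus = m_plus,
                 m_minus = m_minus, lambda = lambda,
                 training_top_n = as.integer(training_top_n),
                 patch_size = as.integer(patch_size),
                 routing_iters = as.integer(routing_iters)),
            class = "classifier_params")
}

# Extract downsampled multi-channel patch features around detections.
# A Gaussian center prior (sigma = patch_size / 3) weights the patch so the
# cell's own territory dominates over encroaching neighbors in crowded
# fields. Patches extending past the border are zero-padded (flag recorded).
extract_patch_features <- function(stack, detections, channels,
                                   patch_size = 32L, ds = 2L) {
  mats <- lapply(channels, function(m) {
    ch <- get_channel(stack, m)
    if (is.null(ch)) stop("channel not in stack: ", m)
    ch$pixels
  })
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  half <- patch_size %/% 2L
  grid <- seq(-half, half - 1, by = ds)
  sigma_w <- patch_size / 3
  wt <- exp(-outer(grid^2, grid^2, `+`) / (2 * sigma_w^2))
  n <- nrow(detections)
  d0 <- length(grid)^2 * length(channels)
  X <- matrix(0, n, d0)
  clipped <- logical(n)
  for (i in seq_len(n)) {
    r <- round(detections$row[i]) + 1 + grid
    c <- round(detections$col[i]) + 1 + grid
    ok_r <- r >= 1 & r <= H; ok_c <- c >= 1 & c <= W
    clipped[i] <- !all(ok_r) || !all(ok_c)
    v <- numeric(0)
    for (m in mats) {
      p <- matrix(0, length(grid), length(grid))
      p[ok_r, ok_c] <- m[r[ok_r], c[ok_c]]
      v <- c(v, as.numeric(p * wt))
    }
    X[i, ] <- v
  }
  attr(X, "clipped") <- clipped
  X
}

#' Build a class-balanced training corpus
#'
#' For each cell type, ranks all detections by the mean intensity of that
#' type's defining marker inside the detection box and keeps the `top_n`
#' brightest (ties broken by lower cell id; fewer than `top_n` candidates
#' are all taken, with a warning). Patches of `patch_size` pixels are
#' extracted around the centroids over the type-marker channel subset.
#'
#' @param detections detection data.frame (from [detect_nuclei()]).
#' @param stack corrected channel stack.
#' @param marker_map named character vector, type -> defining biomarker
#'   (e.g. `c(neuron = "NeuN", astrocyte = "S100b", ...)`).
#' @param top_n cells kept per type (default 5000).
#' @param patch_size patch side in pixels.
#' @return corpus list: `features`, `labels`, `channels`, `patch_size`,
#'   `cell_ids`.
#' @export
build_training_set <- function(detections, stack, marker_map, top_n = 5000L,
                               patch_size = 32L) {
  channels <- unname(marker_map)
  means <- sapply(channels, function(m) {
    px <- get_channel(stack, m)$pixels
    vapply(seq_len(nrow(detections)), function(i) {
      b <- detections[i, c("r0", "c0", "r1", "c1")]
      mean(px[(b$r0 + 1):b$r1, (b$c0 + 1):b$c1])
    }, 0)
  })
  means <- matrix(means, ncol = length(channels),
                  dimnames = list(NULL, channels))
  sel_rows <- integer(0); labels <- character(0)
  for (t in names(marker_map)) {
    mk <- marker_map[[t]]
    ord <- order(-means[, mk], detections$cell_id)
    if (length(ord) < top_n)
      warning("fewer than top_n candidates for type '", t, "': taking all")
    take <- head(ord, top_n)
    sel_rows <- c(sel_rows, take)
    labels <- c(labels, rep(t, length(take)))
  }
  X <- extract_patch_features(stack, detections[sel_rows, , drop = FALSE],
                              channels, patch_size)
  list(features = X, labels = labels, channels = channels,
       patch_size = patch_size, cell_ids = detections$cell_id[sel_rows])
}

# Open-set decision rule: argmax capsule length if it clears the threshold
# (ties broken by fixed class order), else Unknown.
capsule_decision <- function(lengths, classes, threshold) {
  lengths <- matrix(lengths, ncol = length(classes))
  best <- apply(lengths, 1, which.max)   # which.max: first index on ties
  maxlen <- lengths[cbind(seq_len(nrow(lengths)), best)]
  type <- ifelse(maxlen >= threshold, format_type(classes[best]), "Unknown")
  list(type = type, max_length = maxlen, class_index = best)
}

# squash a B x d matrix of capsule pre-activations rowwise
squash <- function(u) {
  n <- sqrt(rowSums(u^2)) + 1e-12
  u * (n / (1 + n^2))
}

# forward pass; returns intermediates needed for backprop
capsnet_forward <- function(state, X, routing_iters = 3L) {
  B <- nrow(X)
  P <- state$P; K <- state$K; dp <- state$dp; dv <- state$dv
  upre <- X %*% state$W1 + matrix(state$b1, B, P * dp, byrow = TRUE)
  u <- vector("list", P)      # squashed primary capsules, each B x dp
  for (p in seq_len(P))
    u[[p]] <- squash(upre[, (p - 1) * dp + seq_len(dp), drop = FALSE])
  # prediction vectors u_hat[[k]][[p]]: B x dv
  uhat <- lapply(seq_len(K), function(k)
    lapply(seq_len(P), function(p) u[[p]] %*% state$W2[[k]][[p]]))
  # dynamic routing
  b <- array(0, c(B, K, P))
  for (it in seq_len(routing_iters)) {
    # softmax over classes k for each (sample, primary)
    eb <- exp(sweep(b, c(1, 3), apply(b, c(1, 3), max)))
    cc <- sweep(eb, c(1, 3), apply(eb, c(1, 3), sum), "/")
    v <- vector("list", K)
    for (k in seq_len(K)) {
      s <- matrix(0, B, dv)
      for (p in seq_len(P)) s <- s + cc[, k, p] * uhat[[k]][[p]]
      v[[k]] <- squash(s)
    }
    if (it < routing_iters) {
      for (k in seq_len(K)) for (p in seq_len(P))
        b[, k, p] <- b[, k, p] + rowSums(uhat[[k]][[p]] * v[[k]])
    }
  }
  lengths <- sapply(v, function(vk) sqrt(rowSums(vk^2)))
  lengths <- matrix(lengths, B, K)
  list(upre = upre, u = u, uhat = uhat, cc = cc, v = v, lengths = lengths)
}

margin_loss <- function(lengths, Tk, m_plus, m_minus, lambda) {
  pos <- clamp(m_plus - lengths, 0, Inf)^2
  neg <- clamp(lengths - m_minus, 0, Inf)^2
  sum(Tk * pos + lambda * (1 - Tk) * neg) / nrow(lengths)
}

# gradient of squash output wrt its input, applied to upstream grad g:
# ds = c(n) g + c'(n)/n * u (u . g)
squash_backprop <- function(u, g) {
  n <- sqrt(rowSums(u^2)) + 1e-12
  cn <- n / (1 + n^2)
  cpn <- (1 - n^2) / (1 + n^2)^2
  g * cn + u * (cpn / n) * rowSums(u * g)
}

capsnet_backward <- function(state, X, fw, Tk, params) {
  B <- nrow(X); P <- state$P; K <- state$K; dp <- state$dp; dv <- state$dv
  L <- fw$lengths
  dL <- (-2 * Tk * clamp(params$m_plus - L, 0, Inf) +
           2 * params$lambda * (1 - Tk) * clamp(L - params$m_minus, 0, Inf)) / B
  gW2 <- lapply(seq_len(K), function(k)
    lapply(seq_len(P), function(p) matrix(0, dp, dv)))
  du <- lapply(seq_len(P), function(p) matrix(0, B, dp))
  for (k in seq_len(K)) {
    vk <- fw$v[[k]]
    nk <- sqrt(rowSums(vk^2)) + 1e-12
    gv <- vk * (dL[, k] / nk)
    # backprop through final squash: s_k = sum_p c u_hat
    sk <- matrix(0, B, dv)
    for (p in seq_len(P)) sk <- sk + fw$cc[, k, p] * fw$uhat[[k]][[p]]
    gs <- squash_backprop(sk, gv)
    for (p in seq_len(P)) {
      guhat <- gs * fw$cc[, k, p]
      gW2[[k]][[p]] <- crossprod(fw$u[[p]], guhat)
      du[[p]] <- du[[p]] + guhat %*% t(state$W2[[k]][[p]])
    }
  }
  gupre <- matrix(0, B, P * dp)
  for (p in seq_len(P)) {
    cols <- (p - 1) * dp + seq_len(dp)
    gupre[, cols] <- squash_backprop(fw$upre[, cols, drop = FALSE], du[[p]])
  }
  list(W1 = crossprod(X, gupre), b1 = colSums(gupre), W2 = gW2)
}

#' Train the capsule-network cell-type classifier
#'
#' Trains with mini-batch Adam on the margin loss. A small fraction of
#' all-absent examples (dark, noise-only patches) is mixed into each batch
#' so that off-manifold inputs drive all capsule lengths low, which the
#' open-set threshold relies on. Deterministic given `seed` up to
#' floating-point rounding.
#'
#' @param corpus training corpus from [build_training_set()].
#' @param params a [classifier_params()].
#' @param seed RNG seed.
#' @param epochs,batch_size,lr optimization controls.
#' @param n_primary,dim_primary,dim_class capsule layout (defaults 16
#'   primary capsules of dim 8, class capsules of dim 16).
#' @param neg_frac fraction of absent-class examples per batch.
#' @param aug_frac fraction of examples per batch overlaid with another
#'   corpus patch shifted to the periphery (crowded-field augmentation: the
#'   label stays with the centered cell, teaching rejection of encroaching
#'   neighbor signal).
#' @return a `capsnet` classifier state.
#' @export
train_capsnet <- function(corpus, params = classifier_params(), seed = 1L,
                          epochs = 20L, batch_size = 64L, lr = 2e-3,
                          n_primary = 16L, dim_primary = 8L, dim_class = 16L,
                          neg_frac = 0.15, aug_frac = 0.3) {
  classes <- sort(unique(corpus$labels))
  if (length(classes) < 2) stop("train_capsnet: single-class corpus")
  K <- length(classes); P <- n_primary; dp <- dim_primary; dv <- dim_class
  scale_ref <- stats::quantile(corpus$features, 0.999)
  if (scale_ref <= 0) scale_ref <- 1
  X <- clamp(corpus$features / scale_ref, 0, 1.5)
  y <- match(corpus$labels, classes)
  d0 <- ncol(X)
  with_seed(seed, {
    state <- list(
      W1 = matrix(rnorm(d0 * P * dp, 0, sqrt(2 / d0)), d0, P * dp),
      b1 = numeric(P * dp),
      W2 = lapply(seq_len(K), function(k)
        lapply(seq_len(P), function(p)
          matrix(rnorm(dp * dv, 0, sqrt(1 / dp)), dp, dv))),
      P = P, K = K, dp = dp, dv = dv, classes = classes,
      scale_ref = scale_ref, channels = corpus$channels,
      patch_size = corpus$patch_size, params = params)
    # Adam state
    zeros_like <- function() list(
      W1 = matrix(0, d0, P * dp), b1 = numeric(P * dp),
      W2 = lapply(seq_len(K), function(k)
        lapply(seq_len(P), function(p) matrix(0, dp, dv))))
    mo <- zeros_like(); ve <- zeros_like()
    step <- 0L
    loss_trace <- numeric(0)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = batch_size)) {
        take <- idx[start:min(n, start + batch_size - 1)]
        Xb <- X[take, , drop = FALSE]
        Tk <- matrix(0, length(take), K)
        Tk[cbind(seq_along(take), y[take])] <- 1
        n_aug <- floor(aug_frac * length(take))
        if (n_aug > 0) {
          g <- as.integer(sqrt(d0 / length(corpus$channels)))
          for (a in seq_len(n_aug)) {
            j <- sample.int(n, 1L)
            sh <- sample(c(-1, 1), 2, replace = TRUE) *
              sample(seq(g %/% 4, g %/% 2), 2, replace = TRUE)
            arr <- array(X[j, ], c(g, g, length(corpus$channels)))
            shifted <- array(0, dim(arr))
            sr <- max(1, 1 + sh[1]):min(g, g + sh[1])
            sc_ <- max(1, 1 + sh[2]):min(g, g + sh[2])
            shifted[sr, sc_, ] <- arr[sr - sh[1], sc_ - sh[2], , drop = FALSE]
            Xb[a, ] <- Xb[a, ] + as.numeric(shifted)
          }
        }
        n_neg <- ceiling(neg_frac * length(take))
        if (n_neg > 0) {
          Xn <- matrix(abs(rnorm(n_neg * d0, 0, 0.02)), n_neg, d0)
          Xb <- rbind(Xb, Xn)
          Tk <- rbind(Tk, matrix(0, n_neg, K))
        }
        fw <- capsnet_forward(state, Xb, params$routing_iters)
        loss <- margin_loss(fw$lengths, Tk, params$m_plus, params$m_minus,
                            params$lambda)
        gr <- capsnet_backward(state, Xb, fw, Tk, params)
        step <- step + 1L
        adam <- function(w, g, m, v) {
          m <- 0.9 * m + 0.1 * g
          v <- 0.999 * v + 0.001 * g^2
          mh <- m / (1 - 0.9^step); vh <- v / (1 - 0.999^step)
          list(w = w - lr * mh / (sqrt(vh) + 1e-8), m = m, v = v)
        }
        a <- adam(state$W1, gr$W1, mo$W1, ve$W1)
        state$W1 <- a$w; mo$W1 <- a$m; ve$W1 <- a$v
        a <- adam(state$b1, gr$b1, mo$b1, ve$b1)
        state$b1 <- a$w; mo$b1 <- a$m; ve$b1 <- a$v
        for (k in seq_len(K)) for (p in seq_len(P)) {
          a <- adam(state$W2[[k]][[p]], gr$W2[[k]][[p]],
                    mo$W2[[k]][[p]], ve$W2[[k]][[p]])
          state$W2[[k]][[p]] <- a$w; mo$W2[[k]][[p]] <- a$m
          ve$W2[[k]][[p]] <- a$v
        }
        ep_loss <- ep_loss + loss; nb <- nb + 1L
      }
      loss_trace <- c(loss_trace, ep_loss / nb)
    }
    state$loss_trace <- loss_trace
    class(state) <- "capsnet"
    state
  })
}

#' Classify detected cells with a trained capsule network
#'
#' Extracts a patch around each detection, runs the capsule forward pass and
#' assigns the class of the longest capsule vector if that length reaches
#' `unknown_threshold`; otherwise the cell is assigned to the unknown class.
#' Ties in the argmax are broken by fixed class order. The full length
#' vector is retained per cell.
#'
#' @param detections detection data.frame.
#' @param stack corrected channel stack.
#' @param state trained [train_capsnet()] classifier.
#' @param params a [classifier_params()] (its `unknown_threshold` is used).
#' @return data.frame `cell_id, type, max_length, clipped` plus one
#'   `len_<class>` column per class.
#' @export
classify_cells <- function(detections, stack, state,
                           params = classifier_params()) {
  X <- extract_patch_features(stack, detections, state$channels,
                              state$patch_size)
  clipped <- attr(X, "clipped")
  X <- clamp(X / state$scale_ref, 0, 1.5)
  n <- nrow(X)
  lengths <- matrix(0, n, state$K)
  for (start in seq(1, n, by = 256)) {
    take <- start:min(n, start + 255)
    fw <- capsnet_forward(state, X[take, , drop = FALSE],
                          state$params$routing_iters)
    lengths[take, ] <- fw$lengths
  }
  dec <- capsule_decision(lengths, state$classes, params$unknown_threshold)
  out <- data.frame(cell_id = detections$cell_id, type = dec$type,
                    max_length = dec$max_length, clipped = clipped)
  len_df <- as.data.frame(lengths)
  names(len_df) <- paste0("len_", state$classes)
  cbind(out, len_df)
}

#' Intensity-threshold baseline classifier
#'
#' For each type-defining marker, thresholds the population histogram of
#' in-box mean intensities (valley between modes when bimodal, Otsu
#' fallback with a warning otherwise). Each cell takes the type of the
#' marker with the largest positive margin above its threshold (margins in
#' population-SD units); cells positive for no marker are Unknown.
#'
#' @inheritParams build_training_set
#' @param expand box expansion factor for the intensity measurement; nucleus
#'   boxes miss somatic and membrane markers (e.g. the RECA1 ring lies
#'   outside an endothelial nucleus box), so means are taken over a
#'   moderately enlarged box.
#' @return data.frame `cell_id, type` plus per-marker margins.
#' @export
baseline_intensity_classify <- function(detections, stack, marker_map,
                                        expand = 1.5) {
  channels <- unname(marker_map)
  n <- nrow(detections)
  margins <- matrix(0, n, length(marker_map),
                    dimnames = list(NULL, names(marker_map)))
  for (t in names(marker_map)) {
    px <- get_channel(stack, marker_map[[t]])$pixels
    H <- nrow(px); W <- ncol(px)
    means <- vapply(seq_len(n), function(i) {
      b <- as.numeric(detections[i, c("r0", "c0", "r1", "c1")])
      hh <- (b[3] - b[1]) / 2 * expand; hw <- (b[4] - b[2]) / 2 * expand
      cr <- (b[1] + b[3]) / 2; cc <- (b[2] + b[4]) / 2
      mean(px[max(1, floor(cr - hh + 1)):min(H, ceiling(cr + hh)),
              max(1, floor(cc - hw + 1)):min(W, ceiling(cc + hw))])
    }, 0)
    thr <- bimodal_threshold(means)
    if (attr(thr, "method") == "otsu")
      warning("unimodal histogram for marker ", marker_map[[t]],
              ": falling back to Otsu")
    s <- sd(means)
    if (!is.finite(s) || s == 0) s <- 1
    margins[, t] <- (means - as.numeric(thr)) / s
  }
  best <- apply(margins, 1, which.max)
  type <- ifelse(margins[cbind(seq_len(n), best)] > 0,
                 format_type(names(marker_map)[best]), "Unknown")
  data.frame(cell_id = detections$cell_id, type = type,
             as.data.frame(margins))
}
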