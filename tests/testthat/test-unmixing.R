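# Disjoint-marker mixing fixture: one bleed donor (S100b -> NeuN), optional
# declared cross-labeling donor (IBA1 -> NeuN).
mix_scene <- function(seed, a_true = 0, b_true = 0) {
  alpha <- matrix(0, 8, 8); beta <- matrix(0, 8, 8)
  alpha[3, 4] <- a_true
  beta[3, 6] <- b_true
  sc <- simulate_scene(scene_params(height = 256, width = 256, n_cells = 45,
                                    seed = seed, panel = panel8,
                                    mixing_alpha = alpha,
                                    crosslabel_beta = beta,
                                    type_proportions = props_disjoint,
                                    min_separation_px = 24))
  list(scene = sc, stack = correct_stack(sc$stack))
}
roi_full <- c(0, 0, 256, 256)

test_that("the nonnegative l1 solver matches closed forms at gamma = 0", {
  set.seed(1)
  x <- rlnorm(500, 8, 1)
  y <- 0.37 * x + rnorm(500, 0, 5)
  a_cd <- mplexpipe:::nnlasso_cd(matrix(x, ncol = 1), y, gamma = 0)
  expect_equal(a_cd, max(0, sum(x * y) / sum(x * x)), tolerance = 1e-6)
  # two orthogonal-ish channels: matches unconstrained least squares when
  # the solution is interior
  x2 <- cbind(c(rlnorm(250, 8, 1), rep(0, 250)),
              c(rep(0, 250), rlnorm(250, 8, 1)))
  y2 <- x2 %*% c(0.2, 0.45) + rnorm(500, 0, 2)
  a2 <- mplexpipe:::nnlasso_cd(x2, y2, gamma = 0)
  expect_equal(a2, as.numeric(coef(lm(y2 ~ x2 - 1))), tolerance = 1e-6)
})

test_that("the solver agrees with an independent lasso implementation", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  n <- 400
  X <- matrix(rlnorm(n * 3, 5, 1), n, 3)
  y <- X %*% c(0.3, 0, 0.1) + rnorm(n, 0, 3)
  gamma <- 2000
  ours <- mplexpipe:::nnlasso_cd(X, y, gamma = gamma)
  # glmnet minimizes 1/(2n) ||y - Xb||^2 + lambda ||b||_1 for standardize=F
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = gamma / (2 * n),
                        lower.limits = 0, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-12)
  theirs <- as.numeric(coef(fit))[-1]
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("an uncorrelated target yields an empty bleed-through set", {
  mx <- fixture("mix_null", function() mix_scene(12))
  est <- estimate_bleedthrough(mx$stack[[3]], mx$stack[c(4, 6, 7, 8)],
                               roi_full)
  expect_true(all(est$alpha < 0.02))
})

test_that("a single 0.30 bleed-through channel is recovered within 0.05", {
  mx <- fixture("mix_030", function() mix_scene(11, a_true = 0.30))
  est <- estimate_bleedthrough(mx$stack[[3]], mx$stack[c(4, 6, 7, 8)],
                               roi_full)
  expect_lt(abs(est$alpha["S100b"] - 0.30), 0.05)
  expect_equal(sum(est$e_bleed), 1L)
})

test_that("small ROIs are rejected", {
  mx <- fixture("mix_null", function() mix_scene(12))
  expect_error(estimate_bleedthrough(mx$stack[[3]], mx$stack[4],
                                     c(0, 0, 20, 20)), "insufficient pixels")
})

test_that("unmixing subtracts declared and automatic donors jointly", {
  mx <- fixture("mix_joint", function()
    mix_scene(13, a_true = 0.25, b_true = 0.15))
  res <- unmix_channel(mx$stack[[3]], mx$stack[c(4, 6, 7, 8)], roi_full,
                       E = "IBA1")
  expect_lt(abs(res$model$alpha["S100b"] - 0.25), 0.05)
  expect_lt(abs(res$model$beta["IBA1"] - 0.15), 0.05)
  # residual close to the true pure signal
  err <- res$corrected$pixels - mx$scene$truth$pure[[3]]
  expect_lt(sd(as.numeric(err)) / diff(range(mx$scene$truth$pure[[3]])), 0.05)
  # output bounded by input, non-negative
  expect_true(all(res$corrected$pixels >= 0))
  expect_true(all(res$corrected$pixels <= mx$stack[[3]]$pixels + 1e-9))
})

test_that("the K-channel budget is always honored", {
  # five genuine contaminants at equal fractions, K = 3
  set.seed(9)
  blobs <- function(centers, H = 80) {
    m <- matrix(0, H, H)
    for (ct in centers) {
      r <- (ct - 1) %/% 8 * 10 + 5; c <- (ct - 1) %% 8 * 10 + 5
      m[max(1, r - 3):min(H, r + 3), max(1, c - 3):min(H, c + 3)] <- rlnorm(1, 9, 0.2)
    }
    m
  }
  donors <- lapply(1:5, function(i) channel_image(blobs(sample(64, 6))))
  target_px <- Reduce(`+`, lapply(donors, function(d) 0.2 * d$pixels))
  target <- channel_image(target_px + matrix(abs(rnorm(6400, 0, 3)), 80, 80))
  res <- unmix_channel(target, donors, c(0, 0, 80, 80), K = 3)
  active <- sum(res$model$alpha > 1e-3) + sum(res$model$beta > 1e-3)
  expect_lte(active, 3L)
  # and with the literal sum-to-K reading the fractions sum to K exactly
  res_lit <- unmix_channel(target, donors, c(0, 0, 80, 80), K = 3,
                           literal_sum_k = TRUE)
  tot <- sum(res_lit$model$alpha) + sum(res_lit$model$beta)
  expect_equal(tot, 3, tolerance = 1e-9)
})

test_that("constrained fit matches an exhaustive grid search on tiny toys", {
  for (seed in 1:3) {
    set.seed(seed)
    x1 <- rlnorm(64, 6, 0.8) * rbinom(64, 1, 0.5)
    x2 <- rlnorm(64, 6, 0.8) * rbinom(64, 1, 0.5)
    y <- 0.23 * x1 + 0.41 * x2 + abs(rnorm(64, 0, 10))
    X <- cbind(x1, x2)
    ours <- mplexpipe:::fit_fractions(X, y, gamma = 0)
    grid <- seq(0, 0.99, by = 0.01)
    best <- c(NA, NA); best_sse <- Inf
    for (a1 in grid) for (a2 in grid) {
      r <- y - a1 * x1 - a2 * x2
      int <- max(0, mean(r))     # profile out the offset term
      sse <- sum((r - int)^2)
      if (sse < best_sse) { best_sse <- sse; best <- c(a1, a2) }
    }
    expect_lt(max(abs(ours - best)), 0.02)
  }
})

test_that("whole-stack unmixing leaves an uncontaminated stack untouched", {
  mx <- fixture("mix_null", function() mix_scene(12))
  um <- unmix_stack(mx$stack, roi = roi_full)
  change <- sum(vapply(seq_along(mx$stack), function(i)
    sum(abs(um$stack[[i]]$pixels - mx$stack[[i]]$pixels)), 0))
  energy <- sum(vapply(mx$stack, function(s) sum(s$pixels), 0))
  expect_lt(change / energy, 0.01)
  # empty E_pairs: no beta anywhere
  expect_true(all(vapply(um$models, function(m)
    is.null(m) || all(m$beta == 0), TRUE)))
})

test_that("degenerate unmixing configurations error clearly", {
  mx <- fixture("mix_null", function() mix_scene(12))
  expect_error(unmix_channel(mx$stack[[3]], mx$stack[4], roi_full,
                             E = 1L, K = 0L), "infeasible")
})

test_that("fitted mixing models serialize to JSON", {
  mx <- fixture("mix_030", function() mix_scene(11, a_true = 0.30))
  res <- unmix_channel(mx$stack[[3]], mx$stack[c(4, 6)], roi_full)
  f <- tempfile(fileext = ".json")
  write_mixing_models(list(`R1:NeuN` = res$model), f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$`R1:NeuN`$alpha$S100b, unname(res$model$alpha["S100b"]),
               tolerance = 1e-12)
})
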