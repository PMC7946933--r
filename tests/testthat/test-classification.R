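test_that("squashing bounds every capsule length in [0, 1]", {
  set.seed(1)
  u <- matrix(rnorm(200 * 16, 0, 10), 200, 16)
  v <- mplexpipe:::squash(u)
  lens <- sqrt(rowSums(v^2))
  expect_true(all(lens >= 0 & lens <= 1))
  # squash direction is preserved
  i <- which.max(rowSums(u^2))
  expect_equal(v[i, ] / sqrt(sum(v[i, ]^2)), u[i, ] / sqrt(sum(u[i, ]^2)),
               tolerance = 1e-6)
})

test_that("classifier parameter invariants are enforced", {
  p <- classifier_params()
  expect_equal(p$unknown_threshold, 0.5)
  expect_equal(p$m_plus, 0.9); expect_equal(p$m_minus, 0.1)
  expect_equal(p$lambda, 0.5); expect_equal(p$training_top_n, 5000L)
  expect_error(classifier_params(m_plus = 1.2))
  expect_error(classifier_params(m_minus = 0.95))
})

test_that("the open-set decision rule thresholds the longest capsule", {
  cls <- c("astrocyte", "neuron", "oligodendrocyte")
  d <- mplexpipe:::capsule_decision(rbind(c(0.9, 0.2, 0.1),
                                          c(0.4, 0.45, 0.3),
                                          c(0.6, 0.6, 0.2)), cls, 0.5)
  expect_identical(d$type, c("Astrocyte", "Unknown", "Astrocyte"))
  expect_equal(d$max_length, c(0.9, 0.45, 0.6))
})

test_that("training-set construction ranks by marker brightness with id ties", {
  tr <- cls_scene(101)
  corpus1 <- suppressWarnings(
    build_training_set(tr$det, tr$stack, marker_map5, top_n = 1))
  expect_equal(nrow(corpus1$features), 5L)
  # the single pick per type carries the brightest in-box marker mean
  px <- mplexpipe:::get_channel(tr$stack, "NeuN")$pixels
  means <- vapply(seq_len(nrow(tr$det)), function(i) {
    b <- tr$det[i, c("r0", "c0", "r1", "c1")]
    mean(px[(b$r0 + 1):b$r1, (b$c0 + 1):b$c1])
  }, 0)
  picked <- corpus1$cell_ids[corpus1$labels == "neuron"]
  expect_equal(picked, tr$det$cell_id[which.max(means)])
  # exact ties resolve to the lower cell id (uniform fake channel)
  fake <- list(channel_image(matrix(100, 512, 512), biomarker = "NeuN"))
  c_tie <- suppressWarnings(
    build_training_set(tr$det, fake, c(neuron = "NeuN"), top_n = 1))
  expect_equal(c_tie$cell_ids, min(tr$det$cell_id))
})

test_that("capsnet training is seed-deterministic and needs >= 2 classes", {
  tr <- cls_scene(101)
  corpus <- suppressWarnings(
    build_training_set(tr$det, tr$stack, marker_map5[1:2], top_n = 10))
  n1 <- train_capsnet(corpus, epochs = 2, seed = 11)
  n2 <- train_capsnet(corpus, epochs = 2, seed = 11)
  expect_identical(n1$loss_trace, n2$loss_trace)
  expect_identical(n1$W1, n2$W1)
  single <- corpus
  single$labels <- rep("neuron", length(single$labels))
  expect_error(train_capsnet(single), "single-class")
})

test_that("held-out capsule accuracy reaches 0.9 and lengths stay in [0,1]", {
  net <- capsnet_trained()
  te <- cls_scene(102)
  pred <- classify_cells(te$det, te$stack, net)
  lens <- as.matrix(pred[, grep("^len_", names(pred))])
  expect_true(all(lens >= 0 & lens <= 1))
  expect_gte(mean(tolower(pred$type) == te$types), 0.9)
  # loss decreased over training
  expect_lt(tail(net$loss_trace, 1), net$loss_trace[1] / 2)
})

test_that("capsule lengths of the matching class separate bimodally", {
  net <- capsnet_trained()
  te <- cls_scene(102)
  pred <- classify_cells(te$det, te$stack, net)
  len_neu <- pred$len_neuron
  # neurons and non-neurons form separated modes: the valley detector finds
  # a threshold and it splits the population consistently with truth
  thr <- mplexpipe:::valley_threshold(len_neu)
  expect_false(is.na(thr))
  expect_gte(mean((len_neu > thr) == (te$types == "neuron")), 0.9)
})

test_that("a never-trained cell type lands in the unknown class", {
  tr <- cls_scene(101)
  net4 <- train_recipe(tr$det, tr$stack, marker_map5[1:4])
  te <- cls_scene(102)
  pred <- classify_cells(te$det, te$stack, net4)
  endo <- te$types == "endothelial"
  expect_gt(sum(endo), 10)
  expect_gte(mean(pred$type[endo] == "Unknown"), 0.8)
})

test_that("baseline thresholding is accurate on clean bimodal expression", {
  te <- cls_scene(102)
  base <- suppressWarnings(
    baseline_intensity_classify(te$det, te$stack, marker_map5))
  expect_gte(mean(tolower(base$type) == te$types), 0.9)
  # an all-zero marker never yields positives
  fake <- c(te$stack, list(channel_image(matrix(0, 512, 512),
                                         biomarker = "Zero")))
  b0 <- suppressWarnings(
    baseline_intensity_classify(te$det, fake,
                                c(marker_map5, ghost = "Zero")))
  expect_true(all(b0$type != "Ghost"))
})

test_that("capsule typing is at least as accurate as the intensity baseline
           on overlap-heavy scenes", {
  ev <- overlap_eval()
  expect_gte(mean(ev$acc_caps), mean(ev$acc_base))
  expect_true(all(ev$acc_caps >= 0.9))
})

test_that("border patches are zero-padded and flagged", {
  te <- cls_scene(102)
  net <- capsnet_trained()
  edge_det <- data.frame(cell_id = 1L, r0 = 0, c0 = 0, r1 = 8, c1 = 8,
                         row = 2, col = 2, score = 0.5)
  pred <- classify_cells(edge_det, te$stack, net)
  expect_true(pred$clipped[1])
})
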