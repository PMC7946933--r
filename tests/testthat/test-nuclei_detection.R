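test_that("nuclear channel fusion sums, preserves DAPI alone, and clips", {
  d <- channel_image(matrix(c(100, 65000), 2, 2))
  h0 <- channel_image(matrix(0, 2, 2))
  expect_equal(fuse_nuclear_channels(d, h0)$pixels, d$pixels)
  h <- channel_image(matrix(65000, 2, 2))
  fused <- fuse_nuclear_channels(d, h)$pixels
  expect_true(all(fused <= 65535))
  expect_equal(fused[2, 1], 65535)
  expect_error(fuse_nuclear_channels(d, channel_image(matrix(0, 3, 3))),
               "geometry")
})

test_that("fusion rescues dropout: fused nuclear signal >= each channel", {
  sc <- fixture("dropout_scene", function()
    simulate_scene(scene_params(height = 384, width = 384, n_cells = 90,
                                seed = 41, dapi_dropout_fraction = 0.25,
                                panel = list(c("DAPI", "Histone")))))
  st <- correct_stack(sc$stack)
  fused <- fuse_nuclear_channels(st[[1]], st[[2]])$pixels
  for (i in sc$truth$cells$cell_id) {
    m <- sc$truth$masks$nucleus == i
    if (!any(m)) next
    expect_gte(mean(fused[m]) + 1e-6,
               max(mean(st[[1]]$pixels[m]), mean(st[[2]]$pixels[m])))
  }
})

test_that("bootstrap segmentation: empty images and sparse scenes", {
  expect_equal(nrow(bootstrap_segment(matrix(0, 64, 64))), 0L)
  sparse <- fixture("sparse_scene", function()
    simulate_scene(scene_params(height = 512, width = 512, n_cells = 100,
                                seed = 8, min_separation_px = 30,
                                dapi_dropout_fraction = 0,
                                panel = list(c("DAPI", "Histone")))))
  st <- correct_stack(sparse$stack)
  det <- bootstrap_segment(fuse_nuclear_channels(st[[1]], st[[2]]))
  ev <- evaluate_detection(det, truth_boxes(sparse$truth))
  expect_gte(ev$recall, 0.95)
  expect_true(all(det$score > 0 & det$score < 1))
})

test_that("densely packed clusters degrade bootstrap recall", {
  sparse <- fixture("sparse_scene", function()
    simulate_scene(scene_params(height = 512, width = 512, n_cells = 100,
                                seed = 8, min_separation_px = 30,
                                dapi_dropout_fraction = 0,
                                panel = list(c("DAPI", "Histone")))))
  dense <- simulate_scene(scene_params(height = 224, width = 224,
                                       n_cells = 100, seed = 8,
                                       min_separation_px = 9,
                                       dapi_dropout_fraction = 0,
                                       panel = list(c("DAPI", "Histone"))))
  recall_of <- function(sc) {
    st <- correct_stack(sc$stack)
    det <- bootstrap_segment(fuse_nuclear_channels(st[[1]], st[[2]]))
    evaluate_detection(det, truth_boxes(sc$truth))$recall
  }
  expect_lt(recall_of(dense), recall_of(sparse))
})

test_that("NMS keeps a single box from near-duplicates", {
  boxes <- rbind(c(10, 10, 30, 30), c(11, 11, 31, 31), c(60, 60, 80, 80))
  keep <- mplexpipe:::nms_boxes(boxes, c(0.9, 0.8, 0.7), iou_thr = 0.3)
  expect_equal(sort(keep), c(1L, 3L))
})

test_that("tiled inference equals whole-image inference", {
  sc <- fixture("tile_scene", function()
    simulate_scene(scene_params(height = 512, width = 512, n_cells = 120,
                                seed = 6, panel = list(c("DAPI", "Histone")))))
  st <- correct_stack(sc$stack)
  whole <- detect_nuclei(st[[1]], st[[2]],
                         params = detection_params(tile = 600, overlap = 64))
  tiled <- detect_nuclei(st[[1]], st[[2]],
                         params = detection_params(tile = 256, overlap = 64))
  expect_equal(nrow(whole), nrow(tiled))
  expect_lte(max(abs(as.matrix(whole[, c("r0", "c0", "r1", "c1")]) -
                       as.matrix(tiled[, c("r0", "c0", "r1", "c1")]))), 1)
  # no surviving pair overlaps above the NMS threshold
  b <- as.matrix(tiled[, c("r0", "c0", "r1", "c1")])
  for (i in seq_len(nrow(b) - 1)) {
    iou <- mplexpipe:::box_iou(b[i, ], b[(i + 1):nrow(b), , drop = FALSE])
    expect_true(all(iou <= 0.3))
  }
})

test_that("a score threshold of 1.0 suppresses all detections", {
  sc <- fixture("tile_scene", function()
    simulate_scene(scene_params(height = 512, width = 512, n_cells = 120,
                                seed = 6, panel = list(c("DAPI", "Histone")))))
  st <- correct_stack(sc$stack)
  det <- detect_nuclei(st[[1]], st[[2]],
                       params = detection_params(score_threshold = 1.0))
  expect_equal(nrow(det), 0L)
  expect_error(detect_nuclei(st[[1]], st[[2]],
                             params = detection_params(tile = 48, overlap = 8)),
               "tile")
})

test_that("detection evaluation: perfect, empty-truth and random baselines", {
  tb <- data.frame(r0 = c(0, 40), c0 = c(0, 40), r1 = c(20, 60),
                   c1 = c(20, 60))
  pred <- cbind(tb, score = 1)
  ev <- evaluate_detection(pred, tb)
  expect_equal(ev$precision, 1); expect_equal(ev$recall, 1)
  expect_equal(ev$auc, 1)
  expect_warning(ev2 <- evaluate_detection(pred, tb[0, ]), "empty truth")
  expect_true(is.nan(ev2$recall))
  # random scores over half-true half-junk predictions: AUC near 0.5
  set.seed(2)
  aucs <- replicate(10, {
    n <- 40
    truth <- data.frame(r0 = seq(0, by = 30, length.out = n), c0 = 0,
                        r1 = seq(20, by = 30, length.out = n), c1 = 20)
    junk <- data.frame(r0 = seq(5, by = 30, length.out = n), c0 = 100,
                       r1 = seq(25, by = 30, length.out = n), c1 = 120)
    pred <- rbind(truth, junk)
    pred$score <- runif(2 * n)
    evaluate_detection(pred, truth)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the learned scoring head reaches recall >= 0.85 held out", {
  mk <- function(seed) {
    sc <- simulate_scene(scene_params(height = 256, width = 256, n_cells = 55,
                                      seed = seed,
                                      panel = list(c("DAPI", "Histone"))))
    st <- correct_stack(sc$stack)
    list(dapi = st[[1]], histone = st[[2]], boxes = truth_boxes(sc$truth))
  }
  trains <- lapply(1:3, mk)
  test_sc <- mk(9)
  expect_error(train_detector(list(), list()), "empty label set")
  expect_warning(
    detc <- train_detector(lapply(trains, function(x) x[c("dapi", "histone")]),
                           lapply(trains, function(x) x$boxes),
                           config = list(backbone_weights = "absent.rds")),
    "cold start")
  det <- detect_nuclei(test_sc$dapi, test_sc$histone, detector = detc)
  ev <- evaluate_detection(det, test_sc$boxes)
  expect_gte(ev$recall, 0.85)
})

test_that("detections serialize to JSON and CSV", {
  det <- data.frame(cell_id = 1:2, r0 = c(0, 10), c0 = c(0, 10),
                    r1 = c(5, 15), c1 = c(5, 15), row = c(2, 12),
                    col = c(2, 12), score = c(0.9, 0.4))
  fj <- tempfile(fileext = ".json")
  write_detections(det, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$score, det$score)
})
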