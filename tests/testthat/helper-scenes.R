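# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# compact two-round panel used by most tests (8 channels)
panel8 <- list(c("DAPI", "Histone", "NeuN", "S100b"),
               c("DAPI", "IBA1", "Olig2", "RECA1"))

# non-endothelial proportions: markers are spatially disjoint, which makes
# bleed-through fractions identifiable (see methods vignette)
props_disjoint <- c(neuron = 0.4, astrocyte = 0.3, oligodendrocyte = 0.2,
                    microglia = 0.1, endothelial = 0)

props_uniform <- c(neuron = 0.2, astrocyte = 0.2, oligodendrocyte = 0.2,
                   microglia = 0.2, endothelial = 0.2)

marker_map5 <- c(neuron = "NeuN", astrocyte = "S100b",
                 oligodendrocyte = "Olig2", microglia = "IBA1",
                 endothelial = "RECA1")

correct_stack <- function(stack, sigma_min = 2, sigma_max = 16) {
  lapply(stack, function(ch) correct_channel(ch, sigma_min, sigma_max)$corrected)
}

# true type of the nearest truth cell for each detection
truth_types_for <- function(detections, truth) {
  vapply(seq_len(nrow(detections)), function(i) {
    d2 <- (truth$cells$row - detections$row[i])^2 +
      (truth$cells$col - detections$col[i])^2
    truth$cells$type[which.min(d2)]
  }, "")
}

# standard mid-size scene with the full default panel, corrected
std_scene <- function() fixture("std_scene", function() {
  sc <- simulate_scene(scene_params(height = 384, width = 384, n_cells = 70,
                                    seed = 31))
  st <- correct_stack(sc$stack)
  det <- detect_nuclei(st[[1]], st[[2]])
  list(scene = sc, stack = st, det = det,
       types = truth_types_for(det, sc$truth))
})

# detected + corrected classification scene (uniform types)
cls_scene <- function(seed, n_cells = 170, sep = 18) {
  fixture(paste0("cls_", seed, "_", n_cells, "_", sep), function() {
    sc <- simulate_scene(scene_params(height = 512, width = 512,
                                      n_cells = n_cells, seed = seed,
                                      panel = panel8,
                                      type_proportions = props_uniform,
                                      min_separation_px = sep))
    st <- correct_stack(sc$stack)
    det <- detect_nuclei(st[[1]], st[[2]])
    list(scene = sc, stack = st, det = det,
         types = truth_types_for(det, sc$truth))
  })
}

# standard training recipe used across classifier tests
train_recipe <- function(det, stack, mm, top_n = 40) {
  corpus <- suppressWarnings(build_training_set(det, stack, mm, top_n = top_n))
  train_capsnet(corpus, epochs = 25, seed = 5, aug_frac = 0.6)
}

capsnet_trained <- function() fixture("capsnet_trained", function() {
  tr <- cls_scene(101)
  train_recipe(tr$det, tr$stack, marker_map5)
})

# capsule-vs-baseline accuracies over three overlap-heavy scenes
overlap_eval <- function() fixture("overlap_eval", function() {
  do.call(rbind, lapply(103:105, function(seed) {
    ov <- cls_scene(seed, n_cells = 230, sep = 11)
    net <- train_recipe(ov$det, ov$stack, marker_map5)
    caps <- classify_cells(ov$det, ov$stack, net)
    base <- suppressWarnings(
      baseline_intensity_classify(ov$det, ov$stack, marker_map5))
    data.frame(seed = seed,
               acc_caps = mean(tolower(caps$type) == ov$types),
               acc_base = mean(tolower(base$type) == ov$types))
  }))
})
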