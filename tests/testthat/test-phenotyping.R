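pheno_fix <- function() fixture("pheno_fix", function() {
  sc <- std_scene()
  cm <- fixture("std_compartments", function()
    build_compartments(sc$stack, sc$det, types = sc$types))
  means <- measure_cells(sc$stack, cm, sc$det)
  calls <- suppressWarnings(call_boolean_phenotypes(means))
  list(sc = sc, cm = cm, means = means, calls = calls)
})

test_that("a uniform channel measures the same mean in every compartment", {
  fx <- pheno_fix()
  flat <- lapply(fx$sc$stack[1:2], function(ch)
    mplexpipe:::set_pixels(ch, matrix(77, 384, 384)))
  m <- measure_cells(flat, fx$cm[c("nucleus", "soma")], fx$sc$det)
  vals <- unlist(m[, -1])
  expect_true(all(is.nan(vals) | abs(vals - 77) < 1e-9))
})

test_that("empty compartments yield NaN, unknown mask ids are fatal", {
  fx <- pheno_fix()
  empty_cyt <- fx$cm
  empty_cyt$cytoplasm <- matrix(0L, 384, 384)
  m <- measure_cells(fx$sc$stack[1:2], empty_cyt[c("nucleus", "cytoplasm")],
                     fx$sc$det)
  expect_true(all(is.nan(m$DAPI.cytoplasm)))
  bad <- fx$cm["nucleus"]
  bad$nucleus[bad$nucleus > 0][1] <- 99999L
  expect_error(measure_cells(fx$sc$stack[1:2], bad, fx$sc$det), "unknown cell")
})

test_that("Boolean calls on bimodal expression reach 95% accuracy", {
  fx <- pheno_fix()
  truth_pos <- fx$sc$types == "neuron"
  expect_gte(mean(fx$calls$call_NeuN == truth_pos), 0.95)
  thr <- attr(fx$calls, "thresholds")
  expect_true(all(c("marker", "threshold", "method") %in% names(thr)))
  # calls reproducible from the logged threshold and the means table
  row <- thr[thr$marker == "NeuN", ]
  v <- fx$means[[paste0("NeuN.", row$compartment)]]
  expect_identical(fx$calls$call_NeuN, is.finite(v) & v > row$threshold)
})

test_that("all-zero markers call negative; manual overrides are verbatim", {
  fx <- pheno_fix()
  means0 <- fx$means
  means0$NeuN.nucleus <- 0
  calls0 <- suppressWarnings(call_boolean_phenotypes(means0))
  expect_true(!any(calls0$call_NeuN))
  manual <- suppressWarnings(call_boolean_phenotypes(
    fx$means, marker_call_config(list(NeuN = list(threshold = 123.45)))))
  thr <- attr(manual, "thresholds")
  expect_equal(thr$threshold[thr$marker == "NeuN"], 123.45)
  expect_identical(thr$method[thr$marker == "NeuN"], "manual")
})

test_that("neuron subtype assignment follows the one-positive rule", {
  rec <- data.frame(cell_id = 1:4, type = c("Neuron", "Neuron", "Neuron",
                                            "Astrocyte"))
  calls <- data.frame(cell_id = 1:4,
                      call_GAD67 = c(TRUE, FALSE, TRUE, FALSE),
                      call_GLUT = c(FALSE, FALSE, TRUE, FALSE))
  attr(calls, "thresholds") <- data.frame(
    marker = c("GAD67", "GLUT"), compartment = "soma",
    threshold = c(100, 100), method = "valley")
  means <- data.frame(cell_id = 1:4, GAD67.soma = c(500, 10, 150, 0),
                      GLUT.soma = c(20, 15, 900, 0))
  out <- assign_neuron_subtypes(rec, calls, means)
  expect_identical(out$subtype,
                   c("GABAergic", "Uncharacterized", "Glutamatergic", NA))
  expect_identical(out$subtype_ambiguous, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("functional flags are independent and warn when markers miss", {
  rec <- data.frame(cell_id = 1:2, type = "Neuron")
  calls <- data.frame(cell_id = 1:2, call_PCNA = c(TRUE, TRUE),
                      call_CC3 = c(FALSE, TRUE))
  out <- assign_functional_states(rec, calls)
  expect_identical(out$proliferating, c(TRUE, TRUE))
  expect_identical(out$apoptotic, c(FALSE, TRUE))
  expect_true(out$proliferating[2] && out$apoptotic[2])
  expect_warning(assign_functional_states(rec, calls[, 1:2, drop = FALSE]),
                 "CC3")
})

test_that("region summaries count by centroid with density per 10^6 px^2", {
  rec <- data.frame(cell_id = 1:6, row = c(5, 5, 5, 25, 25, 25),
                    col = rep(10, 6),
                    type = c("Neuron", "Neuron", "Astrocyte",
                             "Neuron", "Unknown", "Unknown"))
  lab <- matrix(0L, 30, 30)
  lab[1:15, ] <- 4L; lab[16:30, ] <- 9L
  atlas <- region_atlas(lab, c(`4` = "cortex", `9` = "thalamus"))
  s <- summarize_regions(rec, atlas)
  cortex_neu <- s$regions[s$regions$region_id == 4 &
                            s$regions$type == "Neuron", ]
  expect_equal(cortex_neu$count, 2)
  expect_equal(cortex_neu$density_per_1e6px2, 2 * 1e6 / 450)
  expect_equal(sum(s$composition$percent), 100, tolerance = 1e-9)
  # renumbering the labels leaves densities unchanged
  lab2 <- lab; lab2[lab == 4L] <- 70L; lab2[lab == 9L] <- 2L
  s2 <- summarize_regions(rec, region_atlas(lab2, c(`70` = "cortex",
                                                    `2` = "thalamus")))
  expect_equal(sort(s2$regions$density_per_1e6px2),
               sort(s$regions$density_per_1e6px2))
  # one region covering everything captures every cell
  all_lab <- matrix(1L, 30, 30)
  s3 <- summarize_regions(rec, region_atlas(all_lab, c(`1` = "all")))
  expect_equal(sum(s3$regions$count), nrow(rec))
})

test_that("the assembled cell table keeps one row per detection", {
  fx <- pheno_fix()
  cls <- data.frame(cell_id = fx$sc$det$cell_id,
                    type = mplexpipe:::format_type(fx$sc$types))
  tab <- suppressWarnings(
    assemble_cell_table(fx$sc$det, cls, fx$means, fx$calls))
  expect_equal(nrow(tab), nrow(fx$sc$det))
  expect_identical(names(tab)[1:8],
                   c("cell_id", "row", "col", "r0", "c0", "r1", "c1", "type"))
  expect_true(all(is.na(tab$subtype[tab$type != "Neuron"])))
  # round-trips through CSV
  f <- tempfile(fileext = ".csv")
  save_table(tab, f)
  re <- read.csv(f)
  expect_equal(nrow(re), nrow(tab))
})

test_that("rendered PCNA+ fraction is recovered within binomial error", {
  fx <- pheno_fix()
  out <- assign_functional_states(
    data.frame(cell_id = fx$sc$det$cell_id, type = "x"), fx$calls)
  truth <- fx$sc$scene$truth$cells
  match_idx <- vapply(seq_len(nrow(fx$sc$det)), function(i)
    which.min((truth$row - fx$sc$det$row[i])^2 +
                (truth$col - fx$sc$det$col[i])^2), 0L)
  truth_frac <- mean(truth$proliferating[match_idx])
  got_frac <- mean(out$proliferating)
  n <- nrow(fx$sc$det)
  expect_lt(abs(got_frac - truth_frac),
            3 * sqrt(truth_frac * (1 - truth_frac) / n) + 0.02)
})
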