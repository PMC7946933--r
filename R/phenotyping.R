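# Per-cell measurement, Boolean phenotyping and regional quantification.
#
# Compartment masks localize marker measurements: most phenotypic calls
# follow Boolean logic because proteins of interest are either strongly
# expressed or hardly at all, giving bimodal histograms of compartment mean
# intensities. Thresholds are taken at the valley between modes when
# bimodality is detectable, falling back to Otsu; every call's threshold is
# logged so calls are reproducible from the means table alone.

#' Measure per-cell, per-compartment mean marker intensities
#'
#' @param stack corrected channel stack.
#' @param masks compartment label rasters (list of integer matrices, e.g.
#'   from [build_compartments()]; any subset of nucleus / soma / cytoplasm /
#'   membrane / processes).
#' @param detections detection data.frame; every mask label must be a known
#'   cell id.
#' @return data.frame with `cell_id` and one `"<marker>.<compartment>"`
#'   column per pair; empty compartments yield `NaN` (missing, not zero).
#' @export
measure_cells <- function(stack, masks, detections) {
  masks <- masks[intersect(names(masks),
                           c("nucleus", "soma", "cytoplasm", "membrane",
                             "processes"))]
  ids <- detections$cell_id
  for (comp in names(masks)) {
    lab_ids <- unique(masks[[comp]][masks[[comp]] > 0L])
    unknown <- setdiff(lab_ids, ids)
    if (length(unknown))
      stop("mask '", comp, "' references unknown cell ids: ",
           paste(head(unknown, 5), collapse = ", "))
  }
  markers <- unique(stack_biomarkers(stack))
  out <- data.frame(cell_id = ids)
  for (comp in names(masks)) {
    lab <- masks[[comp]]
    idx <- which(lab > 0L)
    labs <- lab[idx]
    counts <- tabulate(match(labs, ids), nbins = length(ids))
    for (m in markers) {
      px <- get_channel(stack, m)$pixels
      sums <- rep(0, length(ids))
      if (length(idx)) {
        agg <- rowsum(px[idx], match(labs, ids))
        sums[as.integer(rownames(agg))] <- agg[, 1]
      }
      out[[paste0(m, ".", comp)]] <- ifelse(counts > 0, sums / counts, NaN)
    }
  }
  out
}

#' Default marker-to-compartment configuration for Boolean calls
#'
#' Nuclear markers are scored over the nucleus mask, somatic markers over
#' the soma mask; PCNA (proliferation) is nuclear and CC3 (apoptosis)
#' somatic by default (overridable).
#'
#' @param overrides named list `marker = list(compartment =, threshold =)`.
#' @return named list of per-marker configs.
#' @export
marker_call_config <- function(overrides = list()) {
  cfg <- list(
    NeuN = list(compartment = "nucleus"), Sox2 = list(compartment = "nucleus"),
    Olig2 = list(compartment = "nucleus"), PCNA = list(compartment = "nucleus"),
    S100b = list(compartment = "soma"), IBA1 = list(compartment = "soma"),
    CNPase = list(compartment = "soma"), RECA1 = list(compartment = "membrane"),
    GLUT = list(compartment = "soma"), GAD67 = list(compartment = "soma"),
    CHAT = list(compartment = "soma"), TH = list(compartment = "soma"),
    CC3 = list(compartment = "soma"))
  for (m in names(overrides))
    cfg[[m]] <- utils::modifyList(cfg[[m]] %||% list(), overrides[[m]])
  cfg
}

#' Threshold compartment means into Boolean phenotype calls
#'
#' Per marker, thresholds the population histogram of the configured
#' compartment's mean intensities (valley between modes when bimodal, Otsu
#' fallback); a manual `threshold` in the config is honored verbatim.
#' Markers measured on fewer than 50 cells trigger an unreliable-threshold
#' warning. Cells whose compartment mean is missing (`NaN`) are called
#' negative.
#'
#' @param means means table from [measure_cells()].
#' @param config a [marker_call_config()].
#' @return data.frame of `call_<marker>` logicals with a `thresholds`
#'   attribute (marker, compartment, threshold, method).
#' @export
call_boolean_phenotypes <- function(means, config = marker_call_config()) {
  out <- data.frame(cell_id = means$cell_id)
  thr_log <- data.frame(marker = character(0), compartment = character(0),
                        threshold = numeric(0), method = character(0))
  for (m in names(config)) {
    comp <- config[[m]]$compartment
    col <- paste0(m, ".", comp)
    if (!col %in% names(means)) next
    v <- means[[col]]
    n_ok <- sum(is.finite(v))
    if (n_ok < 50)
      warning("marker ", m, ": only ", n_ok,
              " measured cells; threshold unreliable")
    if (!is.null(config[[m]]$threshold)) {
      thr <- config[[m]]$threshold
      method <- "manual"
    } else if (all(v[is.finite(v)] == 0)) {
      thr <- Inf                         # all-zero marker: everything negative
      method <- "degenerate"
    } else {
      bt <- bimodal_threshold(v[is.finite(v)])
      thr <- as.numeric(bt)
      method <- attr(bt, "method")
    }
    out[[paste0("call_", m)]] <- is.finite(v) & v > thr
    thr_log[nrow(thr_log) + 1L, ] <- list(m, comp, thr, method)
  }
  attr(out, "thresholds") <- thr_log
  out
}

subtype_marker_map <- c(GLUT = "Glutamatergic", GAD67 = "GABAergic",
                        CHAT = "Cholinergic", TH = "Catecholaminergic")

#' Assign neuronal transmitter subtypes
#'
#' Neurons positive for exactly one transmitter marker take that subtype;
#' zero positives give "Uncharacterized"; multiple positives are resolved
#' by the largest margin above threshold and flagged ambiguous. Non-neurons
#' keep a missing subtype.
#'
#' @param records cell table with a `type` column.
#' @param calls Boolean calls from [call_boolean_phenotypes()].
#' @param means means table (for margin computation on multi-positives).
#' @return `records` with `subtype` and `subtype_ambiguous` columns.
#' @export
assign_neuron_subtypes <- function(records, calls, means) {
  thr_log <- attr(calls, "thresholds")
  records$subtype <- NA_character_
  records$subtype_ambiguous <- FALSE
  present <- names(subtype_marker_map)[
    paste0("call_", names(subtype_marker_map)) %in% names(calls)]
  if (!length(present)) return(records)
  is_neu <- records$type == "Neuron"
  for (i in which(is_neu)) {
    pos <- present[vapply(present, function(m)
      isTRUE(calls[[paste0("call_", m)]][i]), TRUE)]
    if (length(pos) == 0) {
      records$subtype[i] <- "Uncharacterized"
    } else if (length(pos) == 1) {
      records$subtype[i] <- subtype_marker_map[[pos]]
    } else {
      margin <- vapply(pos, function(m) {
        row <- thr_log[thr_log$marker == m, ]
        v <- means[[paste0(m, ".", row$compartment)]][i]
        (v - row$threshold) / max(row$threshold, 1e-9)
      }, 0)
      records$subtype[i] <- subtype_marker_map[[pos[which.max(margin)]]]
      records$subtype_ambiguous[i] <- TRUE
    }
  }
  records
}

#' Assign functional states (proliferation, apoptosis)
#'
#' `proliferating` is the nuclear PCNA call, `apoptotic` the somatic CC3
#' call; the flags are independent (a cell can carry both). A missing
#' marker omits its column with a warning.
#'
#' @param records cell table.
#' @param calls Boolean calls from [call_boolean_phenotypes()].
#' @return `records` with added flag columns.
#' @export
assign_functional_states <- function(records, calls) {
  if ("call_PCNA" %in% names(calls)) records$proliferating <- calls$call_PCNA
  else warning("PCNA not present: proliferating flag omitted")
  if ("call_CC3" %in% names(calls)) records$apoptotic <- calls$call_CC3
  else warning("CC3 not present: apoptotic flag omitted")
  records
}

#' Summarize cell counts and densities per atlas region
#'
#' Each cell is assigned to the region containing its centroid (label 0 =
#' unassigned). Densities are positive-cell counts per 10^6 pixel^2 of
#' region area; the composition table gives global counts and percentages
#' per type (mutually exclusive types plus Unknown sum to 100).
#'
#' @param records cell table with `row`, `col`, `type`.
#' @param atlas a [region_atlas()].
#' @return `list(regions, composition)`: per-region data.frame (region_id,
#'   name, type, count, density_per_1e6px2) and a global composition
#'   data.frame (type, count, percent).
#' @export
summarize_regions <- function(records, atlas) {
  lab <- atlas$labels
  region <- lab[cbind(pmin(nrow(lab), pmax(1, round(records$row) + 1)),
                      pmin(ncol(lab), pmax(1, round(records$col) + 1)))]
  types <- sort(unique(records$type))
  ids <- sort(unique(lab[lab > 0L]))
  rows <- list()
  for (rid in ids) {
    area <- sum(lab == rid)
    for (t in types) {
      cnt <- sum(region == rid & records$type == t)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = rid, name = atlas$names[[as.character(rid)]], type = t,
        count = cnt, density_per_1e6px2 = cnt * 1e6 / area)
    }
  }
  comp <- as.data.frame(table(records$type), stringsAsFactors = FALSE)
  names(comp) <- c("type", "count")
  comp$percent <- 100 * comp$count / max(1, sum(comp$count))
  list(regions = do.call(rbind, rows), composition = comp,
       unassigned = sum(region == 0L))
}

#' Assemble the unified per-cell table
#'
#' Joins detections, classification, compartment means, Boolean calls,
#' neuronal subtypes and functional flags into one row per detected cell
#' (no cell is dropped).
#'
#' @param detections detection data.frame.
#' @param classification output of [classify_cells()] (or a data.frame with
#'   `cell_id`, `type`).
#' @param means means table from [measure_cells()].
#' @param calls Boolean calls from [call_boolean_phenotypes()].
#' @return the cell table, columns in canonical order.
#' @export
assemble_cell_table <- function(detections, classification, means, calls) {
  rec <- merge(detections[, c("cell_id", "row", "col", "r0", "c0", "r1", "c1")],
               classification[, c("cell_id", "type")], by = "cell_id")
  rec <- merge(rec, means, by = "cell_id")
  rec <- assign_neuron_subtypes(rec, calls, means)
  rec <- assign_functional_states(rec, calls)
  call_cols <- setdiff(names(calls), "cell_id")
  rec <- merge(rec, calls[, c("cell_id", call_cols)], by = "cell_id")
  rec <- rec[order(rec$cell_id), ]
  rownames(rec) <- NULL
  attr(rec, "thresholds") <- attr(calls, "thresholds")
  order_cell_columns(rec)
}
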