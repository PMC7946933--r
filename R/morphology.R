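# Sub-cellular compartment masking.
#
# Per-cell masks for nucleus, soma, cytoplasm (soma minus nucleus), plasma
# membrane and cell processes are built from type-specific marker channels.
# Masks are held as integer label rasters (pixel value = cell id);
# 8-connectivity is used throughout (membrane areas depend on this).
# Invariants: nucleus within soma; cytoplasm = soma \ nucleus; membrane
# disjoint from all interior compartments; whole cell = union.

#' Compartment rule table
#'
#' Maps each major cell type to the marker channels delineating its
#' compartments. Defaults follow the standard panel assignments: astrocytes
#' are reconstructed from Sox2 (nucleus), S100b (soma) and GFAP (processes);
#' IBA1 marks microglial soma and processes; NeuN and MAP2 cover neuronal
#' soma and basal arbor; Olig2 (nucleus) and CNPase (soma and processes)
#' reconstruct oligodendrocytes; RECA1 is a validated membrane marker for
#' endothelial cells.
#'
#' @param overrides named list of per-type rule replacements.
#' @return named list: type -> list(nuclear, soma, processes, membrane).
#' @export
compartment_rules <- function(overrides = list()) {
  rules <- list(
    neuron = list(nuclear = "NeuN", soma = "NeuN", processes = "MAP2",
                  membrane = NULL),
    astrocyte = list(nuclear = "Sox2", soma = "S100b", processes = "GFAP",
                     membrane = NULL),
    oligodendrocyte = list(nuclear = "Olig2", soma = "CNPase",
                           processes = "CNPase", membrane = NULL),
    microglia = list(nuclear = NULL, soma = "IBA1", processes = "IBA1",
                     membrane = NULL),
    endothelial = list(nuclear = NULL, soma = NULL, processes = NULL,
                       membrane = "RECA1"))
  for (t in names(overrides)) rules[[t]] <- overrides[[t]]
  rules
}

# Largest connected component of bw containing (or nearest to) point p.
component_at <- function(bw, p) {
  lab <- as_matrix(EBImage::bwlabel(bw))
  l <- lab[p[1], p[2]]
  if (l == 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    d2 <- (idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2
    if (min(d2) > 16) return(NULL)   # nothing near the centroid
    l <- lab[idx[which.min(d2), , drop = FALSE]]
  }
  lab == l
}

inscribed_ellipse <- function(H, W, box) {
  ctr <- c((box[1] + box[3]) / 2, (box[2] + box[4]) / 2)
  ellipse_pixels(H, W, ctr, (box[3] - box[1]) / 2, (box[4] - box[2]) / 2)
}

#' Segment nuclei and somata per detection (classical route)
#'
#' For each detected cell, thresholds the type's nuclear and soma marker
#' channels (fused DAPI + pan-histone when the rule gives no nuclear
#' marker) inside an expanded box window and keeps the connected component
#' at the detection centroid. Cells whose marker window has no foreground
#' get a box-inscribed ellipse nucleus (flagged); an empty soma degenerates
#' to the nucleus (flagged). Pixels already claimed by a previous cell are
#' not overwritten, keeping per-cell masks disjoint.
#'
#' @param stack corrected channel stack (must contain DAPI and Histone for
#'   the fused fallback).
#' @param detections detection data.frame.
#' @param types character vector of cell types per detection (lowercase or
#'   capitalized); `NULL` uses the fused nuclear channel for everything.
#' @param rules a [compartment_rules()] table.
#' @param expand box expansion factor for the segmentation window.
#' @return `list(nucleus, soma, flags)`: two label rasters and a per-cell
#'   flag data.frame.
#' @export
segment_nucleus_soma <- function(stack, detections, types = NULL,
                                 rules = compartment_rules(), expand = 1.6) {
  dapi <- get_channel(stack, "DAPI"); hist <- get_channel(stack, "Histone")
  fused <- if (!is.null(dapi) && !is.null(hist))
    fuse_nuclear_channels(dapi, hist)$pixels
  else if (!is.null(dapi)) dapi$pixels
  else stop("stack has no nuclear channel")
  H <- nrow(fused); W <- ncol(fused)
  nuc_lab <- soma_lab <- matrix(0L, H, W)
  n <- nrow(detections)
  if (is.null(types)) types <- rep(NA_character_, n)
  types <- tolower(types)
  # global thresholds per marker channel (population-level, stable)
  thr_cache <- new.env()
  get_bw <- function(marker) {
    if (is.null(marker)) return(fused > otsu_threshold(as.numeric(fused)))
    key <- marker
    if (!exists(key, thr_cache)) {
      ch <- get_channel(stack, marker)
      bw <- if (is.null(ch)) fused > otsu_threshold(as.numeric(fused))
        else ch$pixels > otsu_threshold(as.numeric(ch$pixels))
      assign(key, bw, thr_cache)
    }
    get(key, thr_cache)
  }
  flags <- data.frame(cell_id = detections$cell_id,
                      nucleus_fallback = FALSE, soma_degenerate = FALSE)
  for (i in seq_len(n)) {
    b <- as.numeric(detections[i, c("r0", "c0", "r1", "c1")])
    ctr <- c(round(detections$row[i]) + 1L, round(detections$col[i]) + 1L)
    half_h <- (b[3] - b[1]) / 2 * expand; half_w <- (b[4] - b[2]) / 2 * expand
    w <- c(max(1, floor(ctr[1] - half_h)), max(1, floor(ctr[2] - half_w)),
           min(H, ceiling(ctr[1] + half_h)), min(W, ceiling(ctr[2] + half_w)))
    rule <- rules[[types[i]]] %||% list(nuclear = NULL, soma = NULL)
    win <- function(bw) bw[w[1]:w[3], w[2]:w[4], drop = FALSE]
    ctr_local <- c(ctr[1] - w[1] + 1L, ctr[2] - w[2] + 1L)
    place <- function(lab_mat, comp_local) {
      idx <- which(comp_local, arr.ind = TRUE)
      if (nrow(idx) == 0) return(lab_mat)
      idx[, 1] <- idx[, 1] + w[1] - 1L; idx[, 2] <- idx[, 2] + w[2] - 1L
      free <- lab_mat[idx] == 0L
      lab_mat[idx[free, , drop = FALSE]] <- detections$cell_id[i]
      lab_mat
    }
    nuc_comp <- component_at(win(get_bw(rule$nuclear)), ctr_local)
    if (is.null(nuc_comp)) {
      flags$nucleus_fallback[i] <- TRUE
      ell <- inscribed_ellipse(H, W, b)
      free <- nuc_lab[ell] == 0L
      nuc_lab[ell[free, , drop = FALSE]] <- detections$cell_id[i]
    } else {
      nuc_lab <- place(nuc_lab, nuc_comp)
    }
    soma_comp <- if (!is.null(rule$soma)) component_at(win(get_bw(rule$soma)),
                                                       ctr_local) else NULL
    if (is.null(soma_comp)) flags$soma_degenerate[i] <- TRUE
    else soma_lab <- place(soma_lab, soma_comp)
  }
  # enforce nucleus subset of soma: soma absorbs its nucleus
  soma_lab[soma_lab == 0L & nuc_lab > 0L] <- nuc_lab[soma_lab == 0L & nuc_lab > 0L]
  nuc_lab[nuc_lab != soma_lab] <- 0L
  list(nucleus = nuc_lab, soma = soma_lab, flags = flags)
}

#' Derive the cytoplasm compartment
#'
#' Cytoplasm is the set difference soma minus nucleus; containment is
#' enforced first by intersecting the nucleus with its soma, so
#' `|soma| = |nucleus| + |cytoplasm|` holds exactly.
#'
#' @param nucleus,soma integer label rasters (or logical masks).
#' @return `list(nucleus, cytoplasm)` label rasters (nucleus clipped).
#' @export
derive_cytoplasm <- function(nucleus, soma) {
  nucleus <- as_label(nucleus); soma <- as_label(soma)
  nuc <- ifelse(nucleus == soma, nucleus, 0L)
  cyt <- ifelse(soma > 0L & nuc != soma, soma, 0L)
  list(nucleus = nuc, cytoplasm = cyt)
}

as_label <- function(m) {
  m <- as_matrix(m)
  storage.mode(m) <- "integer"
  m
}

# -- skeletonization (Zhang-Suen thinning, 8-connectivity) ------------------

#' Topological skeleton of a binary mask
#'
#' Zhang-Suen two-subiteration thinning until stable; preserves
#' 8-connectivity of the foreground.
#'
#' @param bw logical matrix.
#' @return logical matrix of the 1-px-wide skeleton.
#' @export
skeletonize <- function(bw) {
  img <- as_matrix(bw) > 0
  neigh_off <- list(P2 = c(-1, 0), P3 = c(-1, 1), P4 = c(0, 1), P5 = c(1, 1),
                    P6 = c(1, 0), P7 = c(1, -1), P8 = c(0, -1), P9 = c(-1, -1))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- lapply(neigh_off, function(d) shift_matrix(img, -d[1], -d[2]))
      B <- Reduce(`+`, nb)
      seqn <- nb[c("P2", "P3", "P4", "P5", "P6", "P7", "P8", "P9", "P2")]
      A <- matrix(0L, nrow(img), ncol(img))
      for (j in 1:8) A <- A + (!seqn[[j]] & seqn[[j + 1]])
      if (phase == 1) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb$P2 & nb$P4 & nb$P6) & !(nb$P4 & nb$P6 & nb$P8)
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb$P2 & nb$P4 & nb$P8) & !(nb$P2 & nb$P6 & nb$P8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' Extract and assign cell processes
#'
#' Binarizes the arbor channel (bimodal threshold), removes soma territory,
#' skeletonizes the remainder, and assigns each skeleton pixel to the cell
#' whose soma it reaches first by connected-path tracing along the skeleton
#' (synchronous multi-source breadth-first search, 8-connected). A branch
#' bridging two somata is therefore split at its midpoint (equidistant ties
#' go to the lower cell id). Branches touching no soma stay unassigned.
#'
#' @param arbor_channel corrected [channel_image()] or matrix
#'   (GFAP / IBA1 / MAP2 / CNPase, per the rule table).
#' @param soma_lab integer soma label raster.
#' @param threshold optional manual binarization threshold.
#' @param max_steps BFS depth cap (maximum traced arbor length, px).
#' @return integer label raster of process pixels.
#' @export
extract_processes <- function(arbor_channel, soma_lab, threshold = NULL,
                              max_steps = 200L) {
  px <- pixels_of(arbor_channel)
  soma_lab <- as_label(soma_lab)
  proc_lab <- matrix(0L, nrow(px), ncol(px))
  if (diff(range(px)) == 0) return(proc_lab)
  thr <- threshold %||% as.numeric(bimodal_threshold(as.numeric(px)))
  bw <- px > thr
  bw[soma_lab > 0L] <- FALSE
  if (!any(bw)) return(proc_lab)
  skel <- skeletonize(bw)
  if (!any(skel)) return(proc_lab)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  # seed: skeleton pixels near a soma take that soma's id (the skeleton can
  # retract a pixel or two from the soma edge during thinning, so somata are
  # grown by 2 px before seeding)
  grown <- soma_lab
  for (it in 1:2) {
    for (d in shifts) {
      cand <- shift_matrix(grown, d[1], d[2])
      take <- grown == 0L & cand > 0L
      grown[take] <- cand[take]
    }
  }
  lab <- matrix(0L, nrow(px), ncol(px))
  for (d in shifts) {
    cand <- shift_matrix(grown, d[1], d[2])
    take <- skel & lab == 0L & cand > 0L
    lab[take] <- cand[take]
    better <- skel & lab > 0L & cand > 0L & cand < lab
    lab[better] <- cand[better]   # deterministic tie rule: lower id
  }
  for (step in seq_len(max_steps)) {
    grew <- FALSE
    new_lab <- matrix(0L, nrow(px), ncol(px))
    for (d in shifts) {
      cand <- shift_matrix(lab, d[1], d[2])
      take <- skel & lab == 0L & cand > 0L & (new_lab == 0L | cand < new_lab)
      new_lab[take] <- cand[take]
    }
    if (any(new_lab > 0L)) {
      lab[new_lab > 0L] <- new_lab[new_lab > 0L]
      grew <- TRUE
    }
    if (!grew) break
  }
  lab
}

#' Directional-ratio field of a binary mask
#'
#' For every foreground pixel, casts rays in `n_dir` evenly spaced
#' orientations (over 180 degrees, both directions per orientation) and
#' measures the in-mask chord length through the pixel; the ratio is the
#' minimum over maximum chord length. Thin elongated structures (processes)
#' score near 0, blob-like regions (somata) near 1; an isolated pixel
#' scores exactly 1. Values outside the mask are `NA`.
#'
#' @param mask logical matrix.
#' @param n_dir number of ray orientations (default 16).
#' @param max_len maximum traced ray length in pixels.
#' @return numeric matrix of ratios in `[0, 1]` (NA off-mask).
#' @export
directional_ratio <- function(mask, n_dir = 16L, max_len = 30L) {
  m <- as_matrix(mask) > 0
  H <- nrow(m); W <- ncol(m)
  chord_min <- matrix(Inf, H, W); chord_max <- matrix(-Inf, H, W)
  angles <- (seq_len(n_dir) - 1) * pi / n_dir
  for (th in angles) {
    d <- c(sin(th), cos(th))
    run_dir <- function(sgn) {
      acc <- matrix(0L, H, W)
      alive <- m
      for (k in seq_len(max_len)) {
        stp <- round(k * sgn * d)
        alive <- alive & shift_matrix(m, -stp[1], -stp[2])
        if (!any(alive)) break
        acc <- acc + alive
      }
      acc
    }
    chord <- run_dir(1) + run_dir(-1) + 1L
    chord_min <- pmin(chord_min, chord)
    chord_max <- pmax(chord_max, chord)
  }
  out <- chord_min / chord_max
  out[!m] <- NA_real_
  out
}

#' Split a mask into soma and process pixels by directional ratio
#'
#' Pixels whose directional ratio reaches `ratio_threshold` form the soma
#' core; because chords shorten near any boundary, the core is then grown
#' geodesically (within the mask, 8-connected, `reclaim` steps) to reclaim
#' the soma's boundary ring. Everything else in the mask is process.
#'
#' @param mask logical matrix of a whole-cell (soma + processes) stain.
#' @param ratio_threshold pixels with ratio above this are soma-like.
#' @param reclaim geodesic dilation steps for the soma boundary.
#' @inheritParams directional_ratio
#' @return list of logical matrices `soma`, `processes`.
#' @export
split_soma_processes <- function(mask, ratio_threshold = 0.5, n_dir = 16L,
                                 max_len = 30L, reclaim = 3L) {
  m <- as_matrix(mask) > 0
  dr <- directional_ratio(m, n_dir, max_len)
  core <- m & !is.na(dr) & dr >= ratio_threshold
  soma <- core
  for (i in seq_len(reclaim)) {
    grown <- soma
    for (dr_ in -1:1) for (dc_ in -1:1)
      grown <- grown | shift_matrix(soma, dr_, dc_)
    soma <- grown & m
  }
  list(soma = soma, processes = m & !soma)
}

#' Derive the plasma-membrane compartment
#'
#' With a validated membrane marker (e.g. RECA1 for endothelial cells) the
#' marker is thresholded and its pixels (outside interior compartments) are
#' assigned to the nearest cell. Without a marker, the membrane is the
#' 1-pixel 8-connected dilation ring of the combined nucleus + cytoplasm +
#' processes mask (an `n x n` square gains a frame of `4n + 4` pixels).
#'
#' @param nucleus,cytoplasm,processes integer label rasters.
#' @param membrane_marker optional [channel_image()] or matrix.
#' @param threshold optional manual marker threshold.
#' @return integer membrane label raster (disjoint from the inputs).
#' @export
derive_membrane <- function(nucleus, cytoplasm, processes,
                            membrane_marker = NULL, threshold = NULL) {
  nucleus <- as_label(nucleus); cytoplasm <- as_label(cytoplasm)
  processes <- as_label(processes)
  union_lab <- nucleus
  union_lab[cytoplasm > 0L] <- cytoplasm[cytoplasm > 0L]
  union_lab[processes > 0L] <- processes[processes > 0L]
  H <- nrow(union_lab); W <- ncol(union_lab)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  if (!is.null(membrane_marker)) {
    px <- pixels_of(membrane_marker)
    thr <- threshold %||% as.numeric(bimodal_threshold(as.numeric(px)))
    bw <- px > thr & union_lab == 0L
    mem <- matrix(0L, H, W)
    if (!any(bw)) return(mem)
    # assign marker pixels to the nearest cell: labels grow outward from the
    # interior compartments (chessboard distance), marker pixels keep the
    # label that reaches them first
    lab <- union_lab
    for (it in seq_len(64L)) {
      new_lab <- matrix(0L, H, W)
      for (d in shifts) {
        cand <- shift_matrix(lab, d[1], d[2])
        take <- lab == 0L & cand > 0L & (new_lab == 0L | cand < new_lab)
        new_lab[take] <- cand[take]
      }
      if (!any(new_lab > 0L)) break
      lab[new_lab > 0L] <- new_lab[new_lab > 0L]
    }
    mem[bw & lab > 0L] <- lab[bw & lab > 0L]
    return(mem)
  }
  mem <- matrix(0L, H, W)
  for (d in shifts) {
    cand <- shift_matrix(union_lab, d[1], d[2])
    take <- union_lab == 0L & cand > 0L & (mem == 0L | cand < mem)
    mem[take] <- cand[take]
  }
  mem
}

#' Build and validate the full compartment mask set for a scene
#'
#' Convenience wrapper running nucleus/soma segmentation, cytoplasm
#' derivation, process extraction (per arbor channel present in the rule
#' table) and membrane derivation, and enforcing all compartment
#' invariants.
#'
#' @inheritParams segment_nucleus_soma
#' @return list with label rasters `nucleus`, `soma`, `cytoplasm`,
#'   `membrane`, `processes` and the segmentation `flags`.
#' @export
build_compartments <- function(stack, detections, types = NULL,
                               rules = compartment_rules()) {
  seg <- segment_nucleus_soma(stack, detections, types, rules)
  cyt <- derive_cytoplasm(seg$nucleus, seg$soma)
  arbors <- unique(unlist(lapply(rules, function(r) r$processes)))
  proc <- matrix(0L, nrow(seg$soma), ncol(seg$soma))
  for (m in arbors) {
    ch <- get_channel(stack, m)
    if (is.null(ch) || diff(range(ch$pixels)) == 0) next
    p <- extract_processes(ch, seg$soma)
    proc[proc == 0L & p > 0L] <- p[proc == 0L & p > 0L]
  }
  mem_marker <- unique(unlist(lapply(rules, function(r) r$membrane)))
  mem_ch <- if (length(mem_marker)) get_channel(stack, mem_marker[1]) else NULL
  mem <- derive_membrane(cyt$nucleus, cyt$cytoplasm, proc, mem_ch)
  list(nucleus = cyt$nucleus, soma = seg$soma, cytoplasm = cyt$cytoplasm,
       membrane = mem, processes = proc, flags = seg$flags)
}

#' Check compartment invariants for every cell
#'
#' Verifies nucleus within soma, cytoplasm = soma \ nucleus, membrane
#' disjoint from interior compartments, and exact area conservation
#' `|soma| = |nucleus| + |cytoplasm|`.
#'
#' @param masks compartment list from [build_compartments()].
#' @return `TRUE` (invisibly) or an error describing the violated invariant.
#' @export
validate_compartments <- function(masks) {
  nuc <- masks$nucleus; soma <- masks$soma; cyt <- masks$cytoplasm
  mem <- masks$membrane; proc <- masks$processes
  if (any(nuc > 0L & nuc != soma)) stop("nucleus not contained in soma")
  if (any(cyt > 0L & nuc > 0L)) stop("cytoplasm overlaps nucleus")
  if (any(cyt > 0L & cyt != soma)) stop("cytoplasm outside soma")
  if (any(soma > 0L & nuc != soma & cyt != soma))
    stop("soma pixel in neither nucleus nor cytoplasm")
  if (any(mem > 0L & (nuc > 0L | cyt > 0L | proc > 0L)))
    stop("membrane overlaps interior compartments")
  ids <- sort(unique(soma[soma > 0L]))
  for (i in ids) {
    if (sum(soma == i) != sum(nuc == i) + sum(cyt == i))
      stop("area conservation violated for cell ", i)
  }
  invisible(TRUE)
}
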