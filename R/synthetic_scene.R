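# Synthetic multiplex scene generator.
#
# Renders multi-round, multi-channel fluorescence scenes of brain-like tissue
# with complete ground truth: typed cells (nucleus / soma / processes /
# membrane geometry), regionally variable DAPI vs pan-histone labeling,
# smooth illumination and photobleaching fields, autofluorescence texture,
# sensor noise, a sparse cross-channel bleed-through matrix, object-borne
# cross-labeling, and small per-round affine misalignments. Every rendered
# raw channel decomposes exactly (pre-noise) as
#   raw = I_s + I_B + sum_c' alpha[c,c'] I_s^{c'} + sum_c'' beta[c,c''] I_s^{c''}

cell_types <- c("neuron", "astrocyte", "oligodendrocyte", "microglia",
                "endothelial")
neuron_subtypes <- c("Glutamatergic", "GABAergic", "Cholinergic",
                     "Catecholaminergic", "Uncharacterized")

# marker -> (compartment rendered into, cell types expressing it)
marker_catalog <- list(
  DAPI    = list(compartment = "nucleus",   types = cell_types),
  Histone = list(compartment = "nucleus",   types = cell_types),
  NeuN    = list(compartment = "nucleus_soma", types = "neuron"),
  S100b   = list(compartment = "soma",      types = "astrocyte"),
  IBA1    = list(compartment = "soma_processes", types = "microglia"),
  Olig2   = list(compartment = "nucleus",   types = "oligodendrocyte"),
  RECA1   = list(compartment = "membrane",  types = "endothelial"),
  GFAP    = list(compartment = "processes", types = "astrocyte"),
  MAP2    = list(compartment = "soma_processes", types = "neuron"),
  CNPase  = list(compartment = "soma_processes", types = "oligodendrocyte"),
  Sox2    = list(compartment = "nucleus",   types = "astrocyte"),
  GLUT    = list(compartment = "soma",      types = "neuron"),
  GAD67   = list(compartment = "soma",      types = "neuron"),
  CHAT    = list(compartment = "soma",      types = "neuron"),
  TH      = list(compartment = "soma",      types = "neuron"),
  PCNA    = list(compartment = "nucleus",   types = cell_types),
  CC3     = list(compartment = "soma",      types = cell_types)
)

default_panel <- list(
  c("DAPI", "Histone", "NeuN", "S100b", "GFAP"),
  c("DAPI", "IBA1", "Olig2", "CNPase", "RECA1"),
  c("DAPI", "MAP2", "Sox2", "PCNA", "CC3"),
  c("DAPI", "GLUT", "GAD67", "CHAT", "TH")
)

#' Parameters of a synthetic multiplex scene
#'
#' Defaults describe a moderately packed cortical field: ~150 cells on a
#' 512 x 512 raster (0.325 um/px), 20% regional DAPI dropout complemented by
#' pan-histone, 30% illumination non-uniformity, a gentle photobleaching
#' gradient along the acquisition axis, autofluorescence texture and Gaussian
#' sensor noise on the 16-bit scale. Mixing matrices default to zero (no
#' contamination); `round_transforms` default to identity (perfectly aligned
#' rounds).
#'
#' @param height,width raster size in pixels.
#' @param n_cells number of cells to place.
#' @param type_proportions named numeric over the five major types; must sum
#'   to 1.
#' @param nucleus_radius_px length-2 range of nuclear radii in pixels.
#' @param min_separation_px minimum distance between cell centers; lower it
#'   to produce overlap-heavy scenes.
#' @param dapi_dropout_fraction expected fraction of cells with failed DAPI
#'   labeling (regionally structured); pan-histone drops out independently in
#'   complementary regions.
#' @param illumination_amplitude peak-to-trough fractional illumination
#'   non-uniformity in `[0, 1]`.
#' @param bleach_gradient fractional photobleaching loss across the field.
#' @param autofluor_amplitude autofluorescence level (16-bit units).
#' @param noise_sigma Gaussian sensor-noise standard deviation (16-bit units).
#' @param mixing_alpha,crosslabel_beta square channel-by-channel matrices of
#'   bleed-through / cross-labeling fractions (rows = target channel, columns
#'   = source channel, global stack indexing; zero diagonal).
#' @param round_transforms list (one per round) of
#'   `list(rotation_deg, translation, scale)` misalignments; `NULL` entries
#'   mean identity.
#' @param panel list of character vectors: biomarkers imaged in each round.
#' @param expression_level median positive-population intensity (16-bit).
#' @param expression_sdlog log-scale spread of the positive population;
#'   larger values blur the positive/negative separation that intensity
#'   thresholding relies on.
#' @param prolif_fraction,apopt_fraction fractions of PCNA+ / CC3+ cells.
#' @param seed integer RNG seed; scenes are bit-identical given the seed.
#' @return a `scene_params` list.
#' @export
scene_params <- function(height = 512L, width = 512L, n_cells = 150L,
                         type_proportions = c(neuron = 0.35, astrocyte = 0.25,
                                              oligodendrocyte = 0.20,
                                              microglia = 0.12,
                                              endothelial = 0.08),
                         nucleus_radius_px = c(4, 7),
                         min_separation_px = 18,
                         dapi_dropout_fraction = 0.2,
                         illumination_amplitude = 0.3,
                         bleach_gradient = 0.2,
                         autofluor_amplitude = 300,
                         noise_sigma = 50,
                         mixing_alpha = NULL,
                         crosslabel_beta = NULL,
                         round_transforms = NULL,
                         panel = default_panel,
                         expression_level = 15000,
                         expression_sdlog = 0.25,
                         prolif_fraction = 0.10,
                         apopt_fraction = 0.05,
                         seed = 1L) {
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("type_proportions must sum to 1")
  n_ch <- sum(lengths(panel))
  if (is.null(mixing_alpha)) mixing_alpha <- matrix(0, n_ch, n_ch)
  if (is.null(crosslabel_beta)) crosslabel_beta <- matrix(0, n_ch, n_ch)
  if (any(diag(mixing_alpha) != 0) || any(diag(crosslabel_beta) != 0))
    stop("mixing matrices must be zero on the diagonal")
  if (is.null(round_transforms)) round_transforms <- vector("list", length(panel))
  structure(list(height = height, width = width, n_cells = n_cells,
                 type_proportions = type_proportions,
                 nucleus_radius_px = nucleus_radius_px,
                 min_separation_px = min_separation_px,
                 dapi_dropout_fraction = dapi_dropout_fraction,
                 illumination_amplitude = illumination_amplitude,
                 bleach_gradient = bleach_gradient,
                 autofluor_amplitude = autofluor_amplitude,
                 noise_sigma = noise_sigma, mixing_alpha = mixing_alpha,
                 crosslabel_beta = crosslabel_beta,
                 round_transforms = round_transforms, panel = panel,
                 expression_level = expression_level,
                 expression_sdlog = expression_sdlog,
                 prolif_fraction = prolif_fraction,
                 apopt_fraction = apopt_fraction, seed = as.integer(seed)),
            class = "scene_params")
}

# Smooth random field in [0, 1] at spatial scale `scale` pixels.
smooth_field <- function(H, W, scale) {
  scale <- min(scale, floor((min(H, W) - 1) / 8))  # gblur kernel must fit
  f <- as_matrix(EBImage::gblur(matrix(runif(H * W), H, W), sigma = scale))
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0.5, H, W))
  (f - rng[1]) / diff(rng)
}

# Draw an (optionally rotated) filled ellipse into local window; returns
# matrix index pairs (1-based).
ellipse_pixels <- function(H, W, center, a, b, theta = 0) {
  r0 <- max(1, floor(center[1] + 1 - a - b)); r1 <- min(H, ceiling(center[1] + 1 + a + b))
  c0 <- max(1, floor(center[2] + 1 - a - b)); c1 <- min(W, ceiling(center[2] + 1 + a + b))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  rr <- (r0:r1) - 1 - center[1]
  cc <- (c0:c1) - 1 - center[2]
  dr <- matrix(rr, length(rr), length(cc))
  dc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(idx[, 1] + r0 - 1L, idx[, 2] + c0 - 1L)
}

# Random branching walk from a soma boundary; returns pixel index pairs.
branch_walk <- function(H, W, start, angle0, n_steps, branch_prob = 0.04,
                        jitter = 0.25, depth = 2) {
  pts <- matrix(0, 0, 2)
  stack_ <- list(list(p = start, a = angle0, n = n_steps, d = depth))
  while (length(stack_)) {
    cur <- stack_[[length(stack_)]]; stack_[[length(stack_)]] <- NULL
    p <- cur$p; a <- cur$a
    for (i in seq_len(cur$n)) {
      a <- a + rnorm(1, 0, jitter)
      p <- p + c(sin(a), cos(a))
      if (p[1] < 0 || p[1] > H - 1 || p[2] < 0 || p[2] > W - 1) break
      pts <- rbind(pts, round(p))
      if (cur$d > 0 && runif(1) < branch_prob)
        stack_[[length(stack_) + 1L]] <- list(
          p = p, a = a + sample(c(-1, 1), 1) * runif(1, 0.5, 1.2),
          n = ceiling(cur$n / 2), d = cur$d - 1)
    }
  }
  unique(pts + 1)  # to 1-based matrix indices
}

place_cells <- function(params) {
  H <- params$height; W <- params$width
  n <- params$n_cells
  if (n == 0) return(matrix(0, 0, 2))
  sep <- params$min_separation_px
  margin <- 14
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("n_cells too large for scene area (cell overlap budget exceeded)")
    p <- c(runif(1, margin, H - 1 - margin), runif(1, margin, W - 1 - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                           byrow = TRUE))^2))) >= sep)
      centers <- rbind(centers, p)
  }
  centers
}

#' Simulate a multiplex scene with full ground truth
#'
#' Deterministic given `params$seed`. Returns the raw (degraded, per-round
#' misaligned) channel stack together with a `scene_truth` object holding the
#' per-cell table, compartment label rasters, per-channel pure-signal and
#' background rasters, and the applied mixing matrices and transforms.
#'
#' @param params a [scene_params()] object.
#' @return `list(stack = list of channel_image, truth = scene_truth)`.
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, simulate_scene_impl(params))
}

simulate_scene_impl <- function(params) {
  H <- params$height; W <- params$width
  n <- params$n_cells
  centers <- place_cells(params)

  types <- if (n > 0)
    sample(names(params$type_proportions), n, replace = TRUE,
           prob = params$type_proportions) else character(0)

  # regional DAPI / pan-histone dropout: a smooth field phi splits the scene
  # into DAPI-weak vs histone-weak territory
  phi <- smooth_field(H, W, scale = max(32, H / 8))
  dapi_factor <- hist_factor <- rep(1, n)
  nuc_r <- numeric(n); soma_r <- numeric(n); orient <- numeric(n)
  for (i in seq_len(n)) {
    p_phi <- phi[round(centers[i, 1]) + 1, round(centers[i, 2]) + 1]
    f <- params$dapi_dropout_fraction
    if (runif(1) < 2 * f * p_phi) dapi_factor[i] <- 0.05
    if (runif(1) < 2 * f * (1 - p_phi)) hist_factor[i] <- 0.05
    nuc_r[i] <- runif(1, params$nucleus_radius_px[1], params$nucleus_radius_px[2])
    soma_r[i] <- nuc_r[i] * runif(1, 1.6, 2.1)
    orient[i] <- runif(1, 0, pi)
  }

  # subtype / functional assignments
  subtype <- rep(NA_character_, n)
  is_neuron <- types == "neuron"
  subtype[is_neuron] <- sample(neuron_subtypes, sum(is_neuron), replace = TRUE,
                               prob = c(0.5, 0.25, 0.10, 0.10, 0.05))
  proliferating <- runif(n) < params$prolif_fraction
  apoptotic <- runif(n) < params$apopt_fraction

  # compartment label rasters (pixel value = cell_id; later cells win)
  nuc_lab <- soma_lab <- proc_lab <- memb_lab <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    ct <- types[i]
    if (ct == "endothelial") {
      a <- soma_r[i] * runif(1, 2.2, 3.2); b <- soma_r[i] * 0.55
      body <- ellipse_pixels(H, W, centers[i, ], a, b, orient[i])
      inner <- ellipse_pixels(H, W, centers[i, ], a - 1.5, b - 1.5, orient[i])
      soma_lab[body] <- i
      ring <- body[!(paste(body[, 1], body[, 2]) %in%
                       paste(inner[, 1], inner[, 2])), , drop = FALSE]
      memb_lab[ring] <- i
      nucp <- ellipse_pixels(H, W, centers[i, ], nuc_r[i] * 0.9, nuc_r[i] * 0.6,
                             orient[i])
      nuc_lab[nucp] <- i
    } else {
      soma <- ellipse_pixels(H, W, centers[i, ], soma_r[i],
                             soma_r[i] * runif(1, 0.8, 1), orient[i])
      soma_lab[soma] <- i
      nucp <- ellipse_pixels(H, W, centers[i, ], nuc_r[i],
                             nuc_r[i] * runif(1, 0.85, 1), orient[i])
      nuc_lab[nucp] <- i
      n_proc <- switch(ct, neuron = 3L, astrocyte = 4L,
                       oligodendrocyte = 3L, microglia = 4L, 0L)
      for (k in seq_len(n_proc)) {
        a0 <- runif(1, 0, 2 * pi)
        start <- centers[i, ] + soma_r[i] * c(sin(a0), cos(a0))
        pts <- branch_walk(H, W, start, a0, n_steps = round(runif(1, 15, 35)))
        if (nrow(pts)) proc_lab[pts] <- i
      }
    }
  }
  # invariant cleanup: nucleus inside soma; processes/membrane exclusive
  nuc_lab[nuc_lab != soma_lab] <- 0L
  proc_lab[soma_lab != 0L] <- 0L
  memb_lab[nuc_lab != 0L | proc_lab != 0L] <- 0L

  # marker expression levels (lognormal positives, zero negatives)
  markers <- unique(unlist(params$panel))
  expr <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (m in markers) {
    cat_ <- marker_catalog[[m]]
    pos <- types %in% cat_$types
    if (m %in% c("GLUT", "GAD67", "CHAT", "TH")) {
      target <- c(GLUT = "Glutamatergic", GAD67 = "GABAergic",
                  CHAT = "Cholinergic", TH = "Catecholaminergic")[[m]]
      pos <- pos & !is.na(subtype) & subtype == target
    }
    if (m == "PCNA") pos <- proliferating
    if (m == "CC3") pos <- apoptotic
    lv <- rlnorm(sum(pos), log(params$expression_level), params$expression_sdlog)
    expr[pos, m] <- lv
  }
  if ("DAPI" %in% markers) expr[, "DAPI"] <- expr[, "DAPI"] * dapi_factor
  if ("Histone" %in% markers) expr[, "Histone"] <- expr[, "Histone"] * hist_factor

  # pure signal rasters per marker
  comp_pixels <- function(i, comp) {
    which_px <- switch(comp,
      nucleus = nuc_lab == i,
      soma = soma_lab == i,
      nucleus_soma = soma_lab == i,           # nuclear+somatic marker fills soma
      soma_processes = soma_lab == i | proc_lab == i,
      processes = proc_lab == i,
      membrane = memb_lab == i)
    which_px
  }
  pure_marker <- list()
  for (m in markers) {
    canvas <- matrix(0, H, W)
    comp <- marker_catalog[[m]]$compartment
    for (i in which(expr[, m] > 0)) {
      px <- comp_pixels(i, comp)
      canvas[px] <- canvas[px] + expr[i, m]
    }
    if (any(canvas > 0)) canvas <- as_matrix(EBImage::gblur(canvas, 0.8))
    canvas[canvas < 0] <- 0
    pure_marker[[m]] <- canvas
  }

  # background fields
  rr <- matrix(seq_len(H) - 1, H, W); cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  radial <- ((rr - (H - 1) / 2)^2 / (H / 2)^2 + (cc - (W - 1) / 2)^2 / (W / 2)^2)
  illum <- 1 - params$illumination_amplitude * radial / max(radial)
  af_texture <- 0.5 + smooth_field(H, W, scale = max(24, H / 10))

  n_rounds <- length(params$panel)
  ch_names <- character(0)
  for (r in seq_len(n_rounds)) ch_names <- c(ch_names,
    paste0("R", r, ":", params$panel[[r]]))
  n_ch <- length(ch_names)
  alpha <- params$mixing_alpha; beta <- params$crosslabel_beta
  stopifnot(nrow(alpha) == n_ch, nrow(beta) == n_ch)

  pure <- vector("list", n_ch); names(pure) <- ch_names
  backg <- vector("list", n_ch); names(backg) <- ch_names
  k <- 0L
  for (r in seq_len(n_rounds)) for (m in params$panel[[r]]) {
    k <- k + 1L
    pure[[k]] <- pure_marker[[m]]
    bleach <- 1 - params$bleach_gradient * (r - 1) / max(1, n_rounds - 1) -
      0.5 * params$bleach_gradient * cc / max(1, W - 1)
    backg[[k]] <- params$autofluor_amplitude * af_texture * illum * bleach
  }

  # transforms
  transforms <- vector("list", n_rounds)
  center <- c((H - 1) / 2, (W - 1) / 2)
  for (r in seq_len(n_rounds)) {
    tr <- params$round_transforms[[r]]
    transforms[[r]] <- if (is.null(tr)) affine_identity() else
      affine_about_center(center, tr$rotation_deg %||% 0,
                          tr$scale %||% 1, tr$translation %||% c(0, 0))
  }

  # compose raw channels: mix, warp, noise, clip
  stack <- vector("list", n_ch)
  k <- 0L
  for (r in seq_len(n_rounds)) for (m in params$panel[[r]]) {
    k <- k + 1L
    raw <- pure[[k]] + backg[[k]]
    for (src in seq_len(n_ch)) {
      if (alpha[k, src] > 0) raw <- raw + alpha[k, src] * pure[[src]]
      if (beta[k, src] > 0) raw <- raw + beta[k, src] * pure[[src]]
    }
    M <- transforms[[r]]
    if (max(abs(M - affine_identity())) > 0) raw <- warp_affine(raw, M)
    if (params$noise_sigma > 0)
      raw <- raw + rnorm(length(raw), 0, params$noise_sigma)
    raw <- clamp(raw, 0, uint16_max)
    stack[[k]] <- channel_image(raw, channel_id = k, biomarker = m, round_id = r)
  }

  cells <- data.frame(
    cell_id = seq_len(n),
    row = if (n) centers[, 1] else numeric(0),
    col = if (n) centers[, 2] else numeric(0),
    type = types, subtype = subtype,
    proliferating = proliferating, apoptotic = apoptotic,
    nucleus_radius = nuc_r, soma_radius = soma_r,
    dapi_factor = dapi_factor, hist_factor = hist_factor,
    stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(expr))

  truth <- structure(list(
    cells = cells,
    masks = list(nucleus = nuc_lab, soma = soma_lab,
                 processes = proc_lab, membrane = memb_lab),
    pure = pure, background = backg,
    alpha = alpha, beta = beta,
    transforms = transforms, channel_names = ch_names,
    panel = params$panel, params = params), class = "scene_truth")

  list(stack = stack, truth = truth)
}

# Truth bounding boxes (half-open) of nuclei, from the nucleus label raster.
#' Ground-truth nucleus boxes of a synthetic scene
#' @param truth a `scene_truth`.
#' @return data.frame cell_id, r0, c0, r1, c1 (half-open boxes).
#' @export
truth_boxes <- function(truth) {
  lab <- truth$masks$nucleus
  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    data.frame(cell_id = i, r0 = min(idx[, 1]) - 1L, c0 = min(idx[, 2]) - 1L,
               r1 = max(idx[, 1]), c1 = max(idx[, 2]))
  })
  do.call(rbind, out)
}

#' Inject a bright fold-like artifact
#'
#' Adds an additive bright band or blob (spatial scale larger than the ASF
#' `sigma_max`) emulating a tissue fold; the artifact mask is recorded in the
#' `fold_mask` attribute so correction efficacy can be measured.
#'
#' @param image a [channel_image()].
#' @param fold_spec `list(type = "band", col0, width, amplitude)` or
#'   `list(type = "blob", center, radius, amplitude)`.
#' @return degraded [channel_image()] with attribute `fold_mask`.
#' @export
degrade_with_fold <- function(image, fold_spec) {
  px <- image$pixels
  mask <- matrix(FALSE, nrow(px), ncol(px))
  if (fold_spec$type == "band") {
    if (fold_spec$width > 0) {
      c0 <- fold_spec$col0 + 1L
      c1 <- min(ncol(px), c0 + fold_spec$width - 1L)
      mask[, c0:c1] <- TRUE
    }
  } else {
    idx <- ellipse_pixels(nrow(px), ncol(px), fold_spec$center,
                          fold_spec$radius, fold_spec$radius)
    mask[idx] <- TRUE
  }
  px[mask] <- pmin(uint16_max, px[mask] + fold_spec$amplitude)
  out <- set_pixels(image, px)
  attr(out, "fold_mask") <- mask
  out
}

#' Write a simulated scene to disk (TIFF channels + manifest + truth)
#'
#' @param scene result of [simulate_scene()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mf <- data.frame(round_id = integer(0), channel_id = integer(0),
                   biomarker = character(0), fluorophore = character(0),
                   role = character(0), file = character(0))
  for (ch in scene$stack) {
    f <- sprintf("R%d_C%02d_%s.tif", ch$round_id, ch$channel_id, ch$biomarker)
    write_channel_tiff(ch$pixels, file.path(dir, f))
    role <- if (ch$biomarker %in% c("DAPI", "Histone")) "nuclear"
      else if (ch$biomarker %in% c("NeuN", "S100b", "IBA1", "Olig2", "RECA1", "Sox2")) "cell-type"
      else if (ch$biomarker %in% c("GLUT", "GAD67", "CHAT", "TH")) "subtype"
      else if (ch$biomarker %in% c("PCNA", "CC3")) "functional"
      else "arbor"
    mf[nrow(mf) + 1L, ] <- list(ch$round_id, ch$channel_id, ch$biomarker,
                                "synthetic", role, f)
  }
  mpath <- file.path(dir, "manifest.tsv")
  write.table(mf, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(alpha = scene$truth$alpha,
                            beta = scene$truth$beta,
                            channel_names = scene$truth$channel_names),
                       file.path(dir, "truth_mixing.json"))
  invisible(mpath)
}
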