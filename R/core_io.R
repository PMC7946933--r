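#' Channel image container
#'
#' A `channel_image` holds one biomarker's 2-D intensity raster together with
#' its acquisition metadata. Intensities are stored in floating point on the
#' 16-bit scale (0--65535, arbitrary fluorescence units) and must be
#' non-negative. Coordinates throughout the package are 0-based `(row, col)`,
#' pixel-centered; boxes are half-open `[r0, r1) x [c0, c1)`.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param channel_id integer channel index.
#' @param biomarker biomarker name (e.g. `"DAPI"`, `"NeuN"`).
#' @param round_id staining round the channel was acquired in.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_id = 1L, biomarker = "",
                          round_id = 1L, pixel_size_um = 0.325) {
  pixels <- as_matrix(pixels)
  if (any(pixels < 0)) stop("channel_image: intensities must be non-negative")
  if (pixel_size_um <= 0) stop("channel_image: pixel_size_um must be positive")
  structure(
    list(pixels = pixels, channel_id = as.integer(channel_id),
         biomarker = as.character(biomarker), round_id = as.integer(round_id),
         pixel_size_um = pixel_size_um),
    class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s (round %d, channel %d) %d x %d px @ %.3f um\n",
              x$biomarker, x$round_id, x$channel_id,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

# Replace the raster of a channel_image, keeping metadata.
set_pixels <- function(img, pixels) {
  img$pixels <- as_matrix(pixels)
  img
}

#' Read a channel manifest
#'
#' The manifest is a plain-text table (TSV, or YAML with an `entries` list)
#' with columns `round_id`, `channel_id`, `biomarker`, `fluorophore`, `role`
#' and `file`. Roles are one of `nuclear`, `cell-type`, `subtype`,
#' `functional`, `arbor`, `reference`. Each staining round must contain
#' exactly one DAPI entry (the registration reference), and biomarker names
#' must be unique within a round.
#'
#' @param path path to the manifest file.
#' @return a `data.frame` with one row per channel.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(y$entries, function(e) {
      data.frame(round_id = e$round_id, channel_id = e$channel_id,
                 biomarker = e$biomarker, fluorophore = e$fluorophore %||% "",
                 role = e$role, file = e$file %||% "",
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
  }
  required <- c("round_id", "channel_id", "biomarker", "role")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "))
  for (r in unique(df$round_id)) {
    sub <- df[df$round_id == r, ]
    if (sum(sub$biomarker == "DAPI") != 1L)
      stop("manifest round ", r, " must contain exactly one DAPI entry")
    if (anyDuplicated(sub$biomarker))
      stop("manifest round ", r, " has duplicate biomarker names")
  }
  df
}

#' Load a registered channel stack from disk
#'
#' Reads every channel listed in a manifest from 16-bit TIFF files and
#' validates that raster dimensions agree within each round. Rasters larger
#' than `tile_threshold` pixels along either axis are flagged for tiled
#' access (see [image_tiles()]).
#'
#' @param manifest_path path to the channel manifest (see [read_manifest()]).
#' @param image_dir directory containing the TIFF files named in the manifest.
#' @param tile_threshold side length above which tiled access is recommended.
#' @return a list of [channel_image()] objects.
#' @export
load_stack <- function(manifest_path, image_dir, tile_threshold = 4096L) {
  mf <- read_manifest(manifest_path)
  stack <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    f <- file.path(image_dir, mf$file[i])
    if (!file.exists(f))
      stop("channel '", mf$biomarker[i], "' (round ", mf$round_id[i],
           "): file not found: ", f)
    px <- read_channel_tiff(f)
    stack[[i]] <- channel_image(px, mf$channel_id[i], mf$biomarker[i],
                                mf$round_id[i])
    attr(stack[[i]], "tiled") <- any(dim(px) > tile_threshold)
  }
  for (r in unique(mf$round_id)) {
    dims <- unique(lapply(stack[mf$round_id == r], function(x) dim(x$pixels)))
    if (length(dims) > 1)
      stop("dimension mismatch within round ", r)
  }
  stack
}

#' Read / write a 16-bit grayscale TIFF raster
#'
#' Values are stored as 16-bit integers on disk and returned as a numeric
#' matrix on the 0--65535 scale; writing clips to that range.
#'
#' @param path file path.
#' @return `read_channel_tiff`: a numeric matrix.
#' @export
read_channel_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  round(as_matrix(x) * uint16_max)
}

#' @param pixels numeric matrix on the 16-bit scale.
#' @rdname read_channel_tiff
#' @export
write_channel_tiff <- function(pixels, path) {
  px <- clamp(round(as_matrix(pixels)), 0, uint16_max)
  tiff::writeTIFF(px / uint16_max, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Tile decomposition of a raster
#'
#' Splits a raster into overlapping tiles for scalable processing of large
#' mosaics. Tiles carry their offset so results can be mapped back to mosaic
#' coordinates; pixel values on tile overlaps are identical to whole-image
#' access by construction.
#'
#' @param img matrix or [channel_image()].
#' @param tile tile side in pixels.
#' @param overlap overlap between adjacent tiles in pixels (must be < tile).
#' @return list of `list(pixels, r0, c0)` with 0-based offsets.
#' @export
image_tiles <- function(img, tile = 512L, overlap = 64L) {
  if (inherits(img, "channel_image")) img <- img$pixels
  stopifnot(overlap < tile)
  H <- nrow(img); W <- ncol(img)
  step <- tile - overlap
  starts <- function(n) {
    if (n <= tile) return(0L)
    s <- seq(0L, n - tile, by = step)
    if (tail(s, 1) < n - tile) s <- c(s, n - tile)
    s
  }
  out <- list()
  for (r0 in starts(H)) for (c0 in starts(W)) {
    r1 <- min(H, r0 + tile); c1 <- min(W, c0 + tile)
    out[[length(out) + 1L]] <- list(
      pixels = img[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE], r0 = r0, c0 = c0)
  }
  out
}

# Find a channel in a stack by biomarker (optionally round).
get_channel <- function(stack, biomarker, round_id = NULL) {
  for (ch in stack) {
    if (ch$biomarker == biomarker &&
        (is.null(round_id) || ch$round_id == round_id)) return(ch)
  }
  NULL
}

stack_biomarkers <- function(stack) vapply(stack, function(x) x$biomarker, "")

#' Region atlas
#'
#' An integer label raster in registered-stack geometry plus a region-name
#' map. Label 0 is reserved for "unassigned"; every nonzero label must be
#' named.
#'
#' @param labels integer matrix of region labels.
#' @param names named character vector, names = region ids as strings.
#' @return an object of class `region_atlas`.
#' @export
region_atlas <- function(labels, names) {
  labels <- as_matrix(labels)
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  missing <- setdiff(as.character(ids), base::names(names))
  if (length(missing))
    stop("region_atlas: unnamed region labels: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, names = names), class = "region_atlas")
}

#' Read / write a region atlas (label TIFF + JSON name map)
#' @param path_tiff label raster path; `path_json` name-map path.
#' @param path_json JSON file mapping region id to name.
#' @param atlas a [region_atlas()].
#' @export
read_atlas <- function(path_tiff, path_json) {
  labels <- read_channel_tiff(path_tiff)
  nm <- unlist(jsonlite::read_json(path_json))
  region_atlas(labels, nm)
}

#' @rdname read_atlas
#' @export
write_atlas <- function(atlas, path_tiff, path_json) {
  write_channel_tiff(atlas$labels, path_tiff)
  jsonlite::write_json(as.list(atlas$names), path_json, auto_unbox = TRUE)
  invisible(NULL)
}

# Canonical column order of the per-cell table.
cell_table_fixed_cols <- c("cell_id", "row", "col", "r0", "c0", "r1", "c1",
                           "type", "subtype", "proliferating", "apoptotic")

order_cell_columns <- function(df) {
  fixed <- intersect(cell_table_fixed_cols, names(df))
  rest <- setdiff(names(df), fixed)
  df[, c(fixed, sort(rest)), drop = FALSE]
}

#' Export the per-cell measurement table
#'
#' Writes one row per cell with fixed leading columns (id, location, box,
#' type, subtype, functional flags) followed by per-(marker, compartment)
#' mean intensities in alphabetical order. `format = "fcs"` writes the
#' numeric part of the table to a minimal FCS 3.0 container (list mode,
#' 32-bit floats); non-numeric columns are stored as integer category codes.
#'
#' @param records `data.frame` of cell records (may have zero rows).
#' @param path output file.
#' @param format `"csv"` or `"fcs"`.
#' @export
save_table <- function(records, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  records <- order_cell_columns(as.data.frame(records))
  if (format == "csv") {
    ok <- tryCatch({
      write.csv(records, path, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("save_table: cannot write ", path)
    return(invisible(path))
  }
  num <- records
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      if (is.logical(num[[j]])) num[[j]] <- as.numeric(num[[j]])
      else num[[j]] <- as.numeric(factor(num[[j]]))
    }
  }
  write_fcs(as.matrix(num), colnames(num), path)
}

# ---- minimal FCS 3.0 writer / reader --------------------------------------
# List-mode, $DATATYPE=F (32-bit little-endian floats). Enough structure for
# standard cytometry tools to ingest the event matrix.

write_fcs <- function(mat, par_names, path) {
  mat <- as.matrix(mat)
  mat[!is.finite(mat)] <- 0
  n_par <- ncol(mat); n_tot <- nrow(mat)
  text_begin <- 58L
  kw <- c("$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
          "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- par_names[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- sprintf("%.0f", max(1, max(mat[, i], 0)))
  }
  # fixed-width offsets so the TEXT length is stable
  kw["$BEGINDATA"] <- "%BD%"; kw["$ENDDATA"] <- "%ED%"
  build_text <- function(kw) {
    paste0("/", paste0(names(kw), "/", unname(kw), "/", collapse = ""))
  }
  templ <- build_text(kw)
  text_len <- nchar(templ) + 2 * (10 - 4)  # placeholders grow to 10 chars
  data_begin <- text_begin + text_len
  data_end <- data_begin + 4L * n_par * n_tot - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_begin)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text(kw)
  stopifnot(nchar(text) == text_len)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, data_begin - 1L, data_begin, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a minimal FCS file written by [save_table()]
#' @param path FCS file path.
#' @return numeric matrix with parameter names as column names.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L)
  offs <- as.integer(substring(header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6)))
  text <- readChar(con, offs[2] - offs[1] + 1L)
  parts <- strsplit(text, "/", fixed = TRUE)[[1]][-1]
  kw <- setNames(parts[seq(2, length(parts), 2)], parts[seq(1, length(parts), 2)])
  n_par <- as.integer(kw["$PAR"]); n_tot <- as.integer(kw["$TOT"])
  seek(con, offs[3])
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = 4, endian = "little")
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(n_par),
                          function(i) kw[[sprintf("$P%dN", i)]], "")
  mat
}
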