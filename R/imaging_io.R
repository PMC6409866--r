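# Raster containers and lossless image I/O. Rasters are stored as integer
# matrices indexed [y+1, x+1] so that matrix element (1,1) is the top-left
# pixel (0,0) of the image; this matches the row-major layout returned by
# tiff::readTIFF and png::readPNG.

CHANNEL_ROLES <- c("counterstain", "signal_A", "signal_B")

#' Create a single-channel raster
#'
#' A `channel_raster` holds one fluorochrome plane of a field image: an
#' integer pixel matrix, its bit depth (8 or 16), and the role the channel
#' plays in the analysis (`counterstain` defines nuclear shape; `signal_A`
#' and `signal_B` are FISH probe channels).
#'
#' @param pixels Integer matrix of intensities, `[height, width]`, indexed
#'   row = y + 1, column = x + 1 with pixel (0,0) top-left.
#' @param bit_depth Either 8 or 16.
#' @param channel_role One of `"counterstain"`, `"signal_A"`, `"signal_B"`.
#' @return An object of class `channel_raster`.
#' @export
channel_raster <- function(pixels, bit_depth = 8L, channel_role = "counterstain") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("raster dimensions must be positive")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (max(pixels) > 2^bit_depth - 1) stop("intensity exceeds bit depth")
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 channel_role = channel_role),
            class = "channel_raster")
}

#' @export
print.channel_raster <- function(x, ...) {
  cat(sprintf("<channel_raster> %dx%d px, %d-bit, role=%s\n",
              ncol(x$pixels), nrow(x$pixels), x$bit_depth, x$channel_role))
  invisible(x)
}

#' Pixel-size calibration
#'
#' @param microns_per_pixel Physical pixel size in micrometres per pixel;
#'   must be strictly positive. Acquisition metadata, not inferred from data.
#' @return An object of class `calibration`.
#' @export
calibration <- function(microns_per_pixel) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be a single positive number")
  }
  structure(list(microns_per_pixel = microns_per_pixel), class = "calibration")
}

#' Multi-channel field image
#'
#' Bundles the channels captured for one microscope field. All channels must
#' share dimensions and exactly one must be the counterstain.
#'
#' @param channels List of [channel_raster] objects.
#' @param calibration A [calibration] object.
#' @param source_path Provenance string (file the field was read from).
#' @return An object of class `field_image`. Channels are named by role.
#' @export
field_image <- function(channels, calibration, source_path = "<in-memory>") {
  if (length(channels) < 1) stop("at least one channel required")
  if (!all(vapply(channels, inherits, logical(1), "channel_raster"))) {
    stop("channels must be channel_raster objects")
  }
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels must have identical dimensions")
  }
  roles <- vapply(channels, function(ch) ch$channel_role, character(1))
  if (sum(roles == "counterstain") != 1) {
    stop("configuration error: exactly one counterstain channel required")
  }
  if (anyDuplicated(roles)) stop("duplicate channel roles")
  names(channels) <- roles
  structure(list(channels = channels, calibration = calibration,
                 source_path = source_path),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels[[1]]$pixels)
  cat(sprintf("<field_image> %dx%d px, channels: %s, %.4g um/px [%s]\n",
              d[2], d[1], paste(names(x$channels), collapse = ", "),
              x$calibration$microns_per_pixel, x$source_path))
  invisible(x)
}

read_plane_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (ext %in% c("tif", "tiff")) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    lapply(planes, function(p) {
      if (length(dim(p)) == 3) {
        stop("RGB TIFF planes are not supported; supply one plane per channel")
      }
      storage.mode(p) <- "integer"
      p
    })
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    scale <- 2^depth - 1
    if (length(dim(img)) == 2) {
      m <- matrix(as.integer(round(img * scale)), nrow(img), ncol(img))
      attr(m, "bit_depth") <- as.integer(depth)
      list(m)
    } else {
      lapply(seq_len(dim(img)[3]), function(k) {
        m <- matrix(as.integer(round(img[, , k] * scale)), dim(img)[1], dim(img)[2])
        attr(m, "bit_depth") <- as.integer(depth)
        m
      })
    }
  } else {
    stop("unsupported image format: ", path)
  }
}

#' Read a multi-channel field image
#'
#' Reads either a multi-plane TIFF/PNG (one plane per fluorochrome) or a set
#' of single-channel files, and assigns channel roles positionally via
#' `channel_map`. Grayscale planes are never colour-converted.
#'
#' @param path Character vector: one multi-plane file, or one file per channel.
#' @param channel_map Character vector of roles, one per plane/file, e.g.
#'   `c("counterstain", "signal_A")`. Must contain exactly one counterstain.
#' @param cal A [calibration] object.
#' @param bit_depth Bit depth to record when the file metadata does not carry
#'   one (TIFF planes read as integers); default 8 when max intensity < 256,
#'   else 16.
#' @return A [field_image].
#' @export
read_field <- function(path, channel_map, cal, bit_depth = NULL) {
  planes <- if (length(path) == 1) {
    read_plane_file(path)
  } else {
    unlist(lapply(path, read_plane_file), recursive = FALSE)
  }
  if (length(planes) != length(channel_map)) {
    stop("configuration error: channel_map names ", length(channel_map),
         " roles but ", length(planes), " planes were read")
  }
  if (sum(channel_map == "counterstain") != 1) {
    stop("configuration error: channel_map must assign exactly one counterstain")
  }
  channels <- lapply(seq_along(planes), function(k) {
    p <- planes[[k]]
    bd <- attr(p, "bit_depth")
    if (is.null(bd)) bd <- bit_depth
    if (is.null(bd)) bd <- if (max(p) < 256) 8L else 16L
    attr(p, "bit_depth") <- NULL
    channel_raster(p, bit_depth = bd, channel_role = channel_map[k])
  })
  field_image(channels, cal, source_path = paste(path, collapse = ";"))
}

#' Write a raster or composite map to a lossless image file
#'
#' Integer rasters round-trip bit-exactly through TIFF (8- or 16-bit) and
#' PNG (8-bit). Composite maps (frequencies in \[0,1\]) are scaled to the
#' full 16-bit range and the scale is recorded in a JSON sidecar
#' (`<path>.json`, fields `n` and `scale`) so the frequencies are exactly
#' recoverable for populations larger than one byte can resolve.
#'
#' @param raster A [channel_raster] or [composite_map].
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_raster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  if (!dir.exists(dirname(path))) stop("cannot write: directory missing: ", dirname(path))
  if (inherits(raster, "composite_map")) {
    mx <- max(raster$frequencies)
    scale <- if (mx > 0) mx else 1
    px <- matrix(as.integer(round(raster$frequencies / scale * 65535)),
                 nrow(raster$frequencies), ncol(raster$frequencies))
    write_pixels(px, 16L, path, ext)
    jsonlite::write_json(list(n = raster$n_nuclei, scale = scale,
                              probe = raster$probe_label),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else if (inherits(raster, "channel_raster")) {
    write_pixels(raster$pixels, raster$bit_depth, path, ext)
  } else if (is.matrix(raster)) {
    write_pixels(raster, if (max(raster) < 256) 8L else 16L, path, ext)
  } else {
    stop("unsupported raster type")
  }
  invisible(path)
}

write_pixels <- function(px, bit_depth, path, ext) {
  img <- px / (2^bit_depth - 1)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = as.integer(bit_depth))
  } else if (ext == "png") {
    if (bit_depth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit rasters")
    png::writePNG(img, path)
  } else {
    stop("unsupported output format: ", ext)
  }
}

#' Read back a composite map written by [write_raster]
#'
#' @param path Path previously passed to [write_raster] for a composite map.
#' @return A [composite_map] with frequencies restored from the sidecar scale.
#' @export
read_composite <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path, as.is = TRUE)
  composite_map(px / 65535 * side$scale, n_nuclei = side$n,
                probe_label = if (is.null(side$probe)) "" else side$probe,
                target_signature = "", validate_counts = FALSE)
}

#' Render a composite map as a pseudo-colour PNG
#'
#' Uses the perceptually uniform cividis palette; frequency 0 maps to the
#' darkest colour and the map maximum to the brightest.
#'
#' @param cm A [composite_map].
#' @param path Output PNG path.
#' @param n_colours Palette resolution.
#' @export
render_composite_png <- function(cm, path, n_colours = 256) {
  pal <- grDevices::hcl.colors(n_colours, "Cividis")
  mx <- max(cm$frequencies)
  idx <- if (mx > 0) pmin(n_colours, 1 + floor(cm$frequencies / mx * (n_colours - 1))) else
    matrix(1, nrow(cm$frequencies), ncol(cm$frequencies))
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  h <- nrow(cm$frequencies); w <- ncol(cm$frequencies)
  arr <- array(0, c(h, w, 3))
  arr[, , 1] <- matrix(rgb[1, ], h, w)
  arr[, , 2] <- matrix(rgb[2, ], h, w)
  arr[, , 3] <- matrix(rgb[3, ], h, w)
  png::writePNG(arr, path)
  invisible(path)
}
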