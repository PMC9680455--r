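#' Pixel calibration
#'
#' @param pixels_per_mm Pixels per millimetre (default 45, the imaging
#'   resolution the supported printer characterisation used).
#' @return A `pixel_calibration` object.
#' @export
pixel_calibration <- function(pixels_per_mm = 45) {
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0)
    stop("pixel_calibration: pixels_per_mm must be positive", call. = FALSE)
  structure(list(pixels_per_mm = pixels_per_mm), class = "pixel_calibration")
}

#' Convert a pixel count to a physical length
#'
#' Full precision is kept internally; micrometre results are rounded to the
#' nearest integer only when `report = TRUE` (the convention used when
#' quoting printer resolution, e.g. 2 px at 45 px/mm -> 44 um).
#'
#' @param pixels Pixel count (`>= 0`).
#' @param cal A `pixel_calibration` (or a bare pixels-per-mm number).
#' @param unit `"mm"` or `"um"`.
#' @param report Round micrometre output to integer for reporting.
#' @return Length in the requested unit.
#' @export
px_to_length <- function(pixels, cal = pixel_calibration(),
                         unit = c("mm", "um"), report = FALSE) {
  unit <- match.arg(unit)
  if (is.numeric(cal)) cal <- pixel_calibration(cal)
  if (any(pixels < 0)) stop("px_to_length: negative pixel count", call. = FALSE)
  mm <- pixels / cal$pixels_per_mm
  if (unit == "mm") return(mm)
  um <- mm * 1000
  if (report) round(um) else um
}

#' Read a plain-text PGM (P2) image
#'
#' @param path File path to an ASCII PGM image.
#' @return Integer matrix (rows = image rows, origin top-left) with
#'   attribute `maxval`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("read_pgm: no such file: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4 || tok[1] != "P2")
    stop("read_pgm: not an ASCII PGM (P2) file: ", path, call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.integer(tok[4])
  px <- suppressWarnings(as.integer(tok[-(1:4)]))
  if (anyNA(c(w, h, mx)) || length(px) != w * h || anyNA(px))
    stop("read_pgm: truncated or malformed PGM data in ", path, call. = FALSE)
  img <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  attr(img, "maxval") <- mx
  img
}

#' Write a plain-text PGM (P2) image
#'
#' @param img Integer (or integer-valued numeric) matrix.
#' @param path Output path.
#' @param maxval Maximum grey value declared in the header.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  img <- round(img)
  if (any(img < 0) || any(img > maxval))
    stop("write_pgm: pixel values outside [0, maxval]", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Construct a two-channel fluorescence z-stack
#'
#' @param intensities 4-D integer array `[plane, channel, row, col]` of
#'   non-negative intensities.
#' @param channels Character vector naming the channel axis (must contain
#'   the roles' channels; default `c("green", "red")`).
#' @param channel_roles Named list mapping `live`/`dead` to channel names;
#'   green = Calcein (live), red = EthD (dead) by convention.
#' @param z_range_um Axial range spanned by the planes (um).
#' @return A `z_stack` object.
#' @export
z_stack <- function(intensities, channels = c("green", "red"),
                    channel_roles = list(live = "green", dead = "red"),
                    z_range_um = 100) {
  d <- dim(intensities)
  if (length(d) != 4L)
    stop("z_stack: intensities must be [plane, channel, row, col]",
         call. = FALSE)
  if (d[2] != length(channels))
    stop("z_stack: channel axis length != number of channel names",
         call. = FALSE)
  if (any(intensities < 0))
    stop("z_stack: intensities must be non-negative", call. = FALSE)
  if (!all(c("live", "dead") %in% names(channel_roles)) ||
      !all(unlist(channel_roles[c("live", "dead")]) %in% channels))
    stop("z_stack: channel_roles must map live and dead to known channels",
         call. = FALSE)
  structure(list(intensities = intensities, channels = channels,
                 channel_roles = channel_roles,
                 n_planes = d[1], z_range_um = z_range_um),
            class = "z_stack")
}

#' Write / read a z-stack as plain text
#'
#' Multi-page binary TIFF cannot be represented in a text-only deliverable,
#' so stacks are serialised in a simple self-describing ASCII format: a
#' header line `PSTACK n_planes n_channels height width maxval z_range_um`,
#' a line of channel names, then pixel rows in plane-major, channel-minor
#' order.
#'
#' @param stack A `z_stack`.
#' @param path File path.
#' @return `write_stack`: `path`, invisibly. `read_stack`: a `z_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "z_stack"))
  a <- stack$intensities
  d <- dim(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("PSTACK", d[1], d[2], d[3], d[4], max(a, 1),
                   stack$z_range_um), con)
  writeLines(paste(stack$channels, collapse = " "), con)
  for (p in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      writeLines(apply(matrix(a[p, ch, , ], d[3], d[4]), 1, paste,
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_stack
#' @param channel_roles Role mapping applied to the read stack.
#' @export
read_stack <- function(path, channel_roles = list(live = "green", dead = "red")) {
  if (!file.exists(path)) stop("read_stack: no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 7 || hdr[1] != "PSTACK")
    stop("read_stack: not a PSTACK file (expected 'PSTACK P C H W maxval z'): ",
         path, call. = FALSE)
  dims <- as.integer(hdr[2:5])
  channels <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  px <- suppressWarnings(as.integer(scan(
    text = paste(lines[-(1:2)], collapse = " "), what = character(),
    quiet = TRUE)))
  if (length(px) != prod(dims) || anyNA(px))
    stop("read_stack: pixel data does not match declared ",
         dims[1], " planes x ", dims[2], " channels x ",
         dims[3], "x", dims[4], " in ", path, call. = FALSE)
  a <- array(0L, dims)
  i <- 1L
  n <- dims[3] * dims[4]
  for (p in seq_len(dims[1])) {
    for (ch in seq_len(dims[2])) {
      a[p, ch, , ] <- matrix(px[i:(i + n - 1L)], dims[3], dims[4],
                             byrow = TRUE)
      i <- i + n
    }
  }
  z_stack(a, channels = channels, channel_roles = channel_roles,
          z_range_um = as.numeric(hdr[7]))
}

#' Read an image by extension
#'
#' Dispatches on file extension; currently ASCII PGM (`.pgm`) only.
#' @param path File path.
#' @return Integer matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  stop("read_image: unsupported format '", ext,
       "' (text-only build supports .pgm)", call. = FALSE)
}

#' Write records to CSV / a summary to JSON
#'
#' Plain UTF-8 CSV (comma separator, '.' decimal, header row) and JSON with
#' a `schema_version` field, so batch outputs are diffable and replicable.
#'
#' @param records Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @param summary Named list.
#' @export
write_json_summary <- function(summary, path) {
  summary$schema_version <- "1.0"
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Otsu threshold of an integer image
#'
#' Maximises between-class variance over the intensity histogram.
#'
#' @param img Integer matrix (or vector) of intensities in `[0, 255]`.
#' @return Threshold `t`; foreground is conventionally `img > t`.
#' @export
otsu_threshold <- function(img) {
  v <- as.integer(img)
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(h)
  if (n == 0) stop("otsu_threshold: empty image", call. = FALSE)
  levels <- 0:255
  w0 <- cumsum(h)
  mu <- cumsum(h * levels)
  mu_t <- mu[256]
  w1 <- n - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, 256)
  between[ok] <- (mu_t * w0[ok] - n * mu[ok])^2 / (w0[ok] * w1[ok])
  levels[which.max(between)]
}

# internal: label connected components, dropping label 0
label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "logical"
  label_mask_cpp(mask, as.integer(connectivity))
}

# internal: 3x3 box morphological closing of a logical mask
close_mask_3x3 <- function(mask) {
  dilate <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- m
    pad <- function(m, dr, dc) {
      res <- matrix(FALSE, H, W)
      rs <- max(1, 1 + dr):min(H, H + dr)
      cs <- max(1, 1 + dc):min(W, W + dc)
      res[rs, cs] <- m[rs - dr, cs - dc]
      res
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- out | pad(m, dr, dc)
    }
    out
  }
  erode <- function(m) !dilate(!m)
  erode(dilate(mask))
}
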