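# Minimal baseline TIFF I/O.
#
# No TIFF package is available in the target library, so the package carries
# its own reader/writer for the narrow dialect it needs: little-endian,
# uncompressed, single-sample grayscale, 8/16-bit unsigned or 32-bit float,
# multi-page, one strip per page. Physical metadata (pixel size in um, frame
# interval in s) travels in the ImageDescription tag as JSON and in the
# X/YResolution tags (pixels per cm), so the files open in ImageJ/tifffile.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `11` = 4L, `12` = 8L)

#' Write an image stack as a multi-page TIFF
#'
#' Writes a `T x H x W` array (or a single `H x W` matrix) as an uncompressed
#' little-endian grayscale multi-page TIFF. Pixel size and frame interval are
#' stored as JSON in the ImageDescription tag and mirrored in the resolution
#' tags, so round-tripping through [read_tiff_stack()] is lossless.
#'
#' @param x numeric array `T x H x W`, or an `H x W` matrix (one page).
#' @param path output file path.
#' @param dtype `"uint16"` (default), `"uint8"` or `"float32"`. Integer types
#'   are clamped to their range and rounded.
#' @param pixel_size pixel size in micrometers per pixel.
#' @param frame_interval frame interval in seconds.
#' @param extra_description optional named list merged into the JSON metadata.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path, dtype = c("uint16", "uint8", "float32"),
                             pixel_size = 1, frame_interval = 1,
                             extra_description = NULL) {
  dtype <- match.arg(dtype)
  if (is.matrix(x)) dim(x) <- c(1L, nrow(x), ncol(x))
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  Tn <- d[1]; H <- d[2]; W <- d[3]
  bps <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- switch(dtype, uint8 = 1L, uint16 = 1L, float32 = 3L)
  page_bytes <- H * W * (bps %/% 8L)
  if (page_bytes %% 2L == 1L) page_bytes_pad <- page_bytes + 1L else page_bytes_pad <- page_bytes

  desc <- jsonlite::toJSON(
    c(list(pixel_size_um = pixel_size, frame_interval_s = frame_interval,
           n_frames = Tn, dtype = dtype), extra_description),
    auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  # layout: header | page data ... | description | resolution rationals | IFDs
  header_len <- 8L
  data_off <- header_len + (seq_len(Tn) - 1) * page_bytes_pad
  desc_off <- header_len + Tn * page_bytes_pad
  res_off <- desc_off + length(desc_raw)
  ifd0_off <- res_off + 16L
  n_tags_page1 <- 14L
  n_tags_rest <- 13L
  ifd_size <- function(n) 2L + n * 12L + 4L
  ifd_off <- ifd0_off + c(0, cumsum(rep(ifd_size(n_tags_rest), Tn)))[seq_len(Tn)]
  ifd_off[1] <- ifd0_off
  if (Tn > 1) {
    ifd_off <- ifd0_off + cumsum(c(0L, rep(ifd_size(n_tags_rest), Tn - 1L)))
    ifd_off <- ifd_off + c(0L, rep(ifd_size(n_tags_page1) - ifd_size(n_tags_rest), Tn - 1L))
    # first IFD has one extra tag (ImageDescription); later IFDs start after it
    ifd_off <- ifd0_off + c(0L, ifd_size(n_tags_page1) +
                              (seq_len(Tn - 1L) - 1L) * ifd_size(n_tags_rest))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")

  u16 <- function(v) {
    v <- as.integer(round(v))
    v[v > 32767L] <- v[v > 32767L] - 65536L
    v
  }
  for (t in seq_len(Tn)) {
    page <- as.vector(t(x[t, , ]))  # row-major
    if (dtype == "uint8") {
      writeBin(as.raw(clamp(round(page), 0, 255)), con)
    } else if (dtype == "uint16") {
      writeBin(u16(clamp(page, 0, 65535)), con, size = 2, endian = "little")
    } else {
      writeBin(as.double(page), con, size = 4, endian = "little")
    }
    if (page_bytes_pad > page_bytes) writeBin(as.raw(0L), con)
  }
  writeBin(desc_raw, con)
  # X and Y resolution in pixels per cm as a rational
  res_num <- as.integer(round(1e7 / pixel_size))
  writeBin(c(res_num, 1000L, res_num, 1000L), con, size = 4, endian = "little")

  tag <- function(code, type, count, value) {
    writeBin(as.integer(code), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {  # SHORT packed left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (t in seq_len(Tn)) {
    first <- t == 1L
    ntags <- if (first) n_tags_page1 else n_tags_rest
    writeBin(as.integer(ntags), con, size = 2, endian = "little")
    tag(256L, 4L, 1L, W)
    tag(257L, 4L, 1L, H)
    tag(258L, 3L, 1L, bps)
    tag(259L, 3L, 1L, 1L)
    tag(262L, 3L, 1L, 1L)
    if (first) tag(270L, 2L, length(desc_raw), desc_off)
    tag(273L, 4L, 1L, data_off[t])
    tag(277L, 3L, 1L, 1L)
    tag(278L, 4L, 1L, H)
    tag(279L, 4L, 1L, page_bytes)
    tag(282L, 5L, 1L, res_off)
    tag(283L, 5L, 1L, res_off + 8L)
    tag(296L, 3L, 1L, 3L)
    tag(339L, 3L, 1L, fmt)
    nxt <- if (t < Tn) ifd_off[t + 1L] else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads the TIFF dialect written by [write_tiff_stack()] (plus any baseline
#' uncompressed little-endian grayscale TIFF with one sample per pixel).
#'
#' @param path file path.
#' @return list with `data` (`T x H x W` array), `pixel_size`,
#'   `frame_interval`, `dtype` and `description` (parsed JSON list or raw
#'   string).
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop("not a TIFF file: ", path)
  order <- rawToChar(raw_all[1:2])
  if (order != "II") stop("only little-endian ('II') TIFF is supported")
  u32 <- function(off) {
    v <- readBin(raw_all[(off + 1):(off + 4)], "integer", size = 4,
                 endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }
  u16 <- function(off) {
    readBin(raw_all[(off + 1):(off + 2)], "integer", size = 2,
            endian = "little", signed = FALSE)
  }
  if (u16(2) != 42) stop("bad TIFF magic")

  pages <- list()
  ifd <- u32(4)
  desc <- NULL
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + (k - 1) * 12
      code <- u16(e)
      type <- u16(e + 2)
      count <- u32(e + 4)
      sz <- TIFF_TYPE_SIZES[as.character(type)]
      total <- sz * count
      voff <- if (!is.na(total) && total <= 4) e + 8 else u32(e + 8)
      vals <- NULL
      if (!is.na(sz)) {
        if (type == 2L) {
          bytes <- raw_all[(voff + 1):(voff + count)]
          bytes <- bytes[seq_len(max(0L, which(bytes == as.raw(0L))[1] - 1L))]
          vals <- rawToChar(bytes)
        } else if (type == 3L) {
          vals <- vapply(seq_len(count), function(i) u16(voff + (i - 1) * 2), 0)
        } else if (type == 4L) {
          vals <- vapply(seq_len(count), function(i) u32(voff + (i - 1) * 4), 0)
        } else if (type == 5L) {
          vals <- vapply(seq_len(count), function(i)
            u32(voff + (i - 1) * 8) / u32(voff + (i - 1) * 8 + 4), 0)
        }
      }
      tags[[as.character(code)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    if (is.null(desc) && !is.null(tags[["270"]])) desc <- tags[["270"]]
    ifd <- u32(ifd + 2 + n * 12)
  }
  if (!length(pages)) stop("TIFF contains no pages")

  t1 <- pages[[1]]
  W <- as.integer(t1[["256"]]); H <- as.integer(t1[["257"]])
  bps <- as.integer(t1[["258"]] %||% 1)
  comp <- as.integer(t1[["259"]] %||% 1)
  fmt <- as.integer(t1[["339"]] %||% 1)
  if (comp != 1L) stop("only uncompressed TIFF is supported")
  if (!is.null(t1[["277"]]) && as.integer(t1[["277"]]) != 1L)
    stop("only single-sample grayscale TIFF is supported")

  Tn <- length(pages)
  # fast path: every page one strip, all strips contiguous and equal-sized
  offs1 <- vapply(pages, function(tg) tg[["273"]][1], 0)
  cnts1 <- vapply(pages, function(tg) tg[["279"]][1], 0)
  one_strip <- all(vapply(pages, function(tg) length(tg[["273"]]) == 1L, TRUE))
  pad <- cnts1[1] + (cnts1[1] %% 2)
  contiguous <- one_strip && all(cnts1 == cnts1[1]) &&
    (Tn == 1L || all(diff(offs1) == pad))
  if (contiguous && bps %in% c(8L, 16L, 32L)) {
    n_all <- Tn * H * W
    buf <- raw_all[(offs1[1] + 1):(offs1[1] + Tn * pad)]
    if (pad != cnts1[1]) {
      dim(buf) <- c(pad, Tn)
      buf <- as.vector(buf[seq_len(cnts1[1]), ])
    }
    v <- if (fmt == 3L && bps == 32L) {
      readBin(buf, "double", n = n_all, size = 4, endian = "little")
    } else if (bps == 16L) {
      readBin(buf, "integer", n = n_all, size = 2, endian = "little",
              signed = FALSE)
    } else as.integer(buf[seq_len(n_all)])
    out <- aperm(array(as.double(v), dim = c(W, H, Tn)), c(3, 2, 1))
  } else {
  out <- array(0, dim = c(Tn, H, W))
  for (t in seq_len(Tn)) {
    tg <- pages[[t]]
    offs <- tg[["273"]]
    cnts <- tg[["279"]]
    buf <- raw(sum(cnts))
    pos <- 1L
    for (s in seq_along(offs)) {
      buf[pos:(pos + cnts[s] - 1)] <- raw_all[(offs[s] + 1):(offs[s] + cnts[s])]
      pos <- pos + cnts[s]
    }
    if (fmt == 3L && bps == 32L) {
      v <- readBin(buf, "double", n = H * W, size = 4, endian = "little")
    } else if (bps == 16L) {
      v <- readBin(buf, "integer", n = H * W, size = 2, endian = "little",
                   signed = FALSE)
    } else if (bps == 8L) {
      v <- as.integer(readBin(buf, "raw", n = H * W))
    } else stop("unsupported TIFF bit depth: ", bps)
    out[t, , ] <- matrix(as.double(v), H, W, byrow = TRUE)
  }
  }

  meta <- NULL
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  }
  px <- meta$pixel_size_um %||% {
    xr <- t1[["282"]]
    if (!is.null(xr) && is.finite(xr) && xr > 0) 1e4 / xr else 1
  }
  list(data = out,
       pixel_size = px,
       frame_interval = meta$frame_interval_s %||% 1,
       dtype = if (fmt == 3L) "float32" else paste0("uint", bps),
       description = meta %||% desc)
}
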