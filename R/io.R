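#' @name volume-io
#' @title Read and write volumes (TIFF stacks, MHD/RAW)
#'
#' @description
#' Minimal, dependency-free readers and writers for the two volume formats
#' used by the pipeline: multi-page uncompressed little-endian TIFF (one
#' slice per page, grayscale, 8/16/32-bit unsigned or 32/64-bit float) and
#' MetaImage MHD/RAW.  Voxel spacing and origin survive the round trip: the
#' TIFF writer stores them as JSON in the ImageDescription tag, the MHD
#' header carries them natively.  Both writers emit the x-fastest element
#' order conventional for these formats and the readers permute back to this
#' package's `[z, y, x]` arrays.
NULL

TIFF_TYPES <- list(
  uint8   = list(bits = 8L,  fmt = 1L, size = 1L),
  uint16  = list(bits = 16L, fmt = 1L, size = 2L),
  uint32  = list(bits = 32L, fmt = 1L, size = 4L),
  float32 = list(bits = 32L, fmt = 3L, size = 4L),
  float64 = list(bits = 64L, fmt = 3L, size = 8L))

auto_dtype <- function(arr) {
  if (is.integer(arr)) {
    m <- suppressWarnings(max(0L, max(arr)))
    if (m <= 255L) "uint8" else if (m <= 65535L) "uint16" else "uint32"
  } else "float64"
}

# 12-byte IFD entry; values must already be encoded little-endian
tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4)
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    value_raw, rep(as.raw(0), 4 - length(value_raw)))
}

le4 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
le2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

encode_pixels <- function(page_rowmajor, dtype) {
  tp <- TIFF_TYPES[[dtype]]
  if (tp$fmt == 3L) {
    writeBin(as.double(page_rowmajor), raw(), size = tp$size,
             endian = "little")
  } else if (dtype == "uint8") {
    as.raw(as.integer(page_rowmajor))
  } else {
    x <- as.numeric(page_rowmajor)
    if (dtype == "uint16") {
      x <- ifelse(x > 32767, x - 65536, x) # reinterpret as signed for writeBin
    } else {
      x <- ifelse(x > 2147483647, x - 4294967296, x)
    }
    writeBin(as.integer(x), raw(), size = tp$size, endian = "little")
  }
}

#' @rdname volume-io
#' @param v `Volume3D` (for writing).
#' @param path file path; extension selects the format in [write_volume()].
#' @param dtype `"auto"` (integer data to uint8/16/32, doubles to float64) or
#'   one of `"uint8"`, `"uint16"`, `"uint32"`, `"float32"`, `"float64"`.
#' @export
write_tiff_volume <- function(v, path, dtype = "auto") {
  stopifnot(is_volume3d(v))
  if (dtype == "auto") dtype <- auto_dtype(v$voxels)
  tp <- TIFF_TYPES[[dtype]]
  if (is.null(tp)) stop("unsupported dtype: ", dtype, call. = FALSE)
  d <- dim(v$voxels)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  desc <- c(charToRaw(as.character(jsonlite::toJSON(list(
    spacing_nm = v$spacing, origin_nm = v$origin), auto_unbox = TRUE,
    digits = NA))), as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), le2(42L), le4(8L)), con)
  offset <- 8L
  n_entries <- 10L
  ifd_size <- 2L + 12L * n_entries + 4L
  strip_bytes <- ny * nx * tp$size
  for (z in seq_len(nz)) {
    desc_here <- if (z == 1L) desc else raw(0)
    desc_off <- offset + ifd_size
    data_off <- desc_off + length(desc_here)
    next_off <- if (z < nz) data_off + strip_bytes else 0L
    entries <- c(
      tiff_entry(256L, 4L, 1L, le4(nx)),
      tiff_entry(257L, 4L, 1L, le4(ny)),
      tiff_entry(258L, 3L, 1L, le2(tp$bits)),
      tiff_entry(259L, 3L, 1L, le2(1L)),            # no compression
      tiff_entry(262L, 3L, 1L, le2(1L)),            # black is zero
      if (length(desc_here))
        tiff_entry(270L, 2L, length(desc_here), le4(desc_off))
      else
        tiff_entry(270L, 2L, 1L, c(as.raw(0), raw(3))),
      tiff_entry(273L, 4L, 1L, le4(data_off)),
      tiff_entry(278L, 4L, 1L, le4(ny)),
      tiff_entry(279L, 4L, 1L, le4(strip_bytes)),
      tiff_entry(339L, 3L, 1L, le2(tp$fmt)))
    writeBin(c(le2(n_entries), entries, le4(next_off)), con)
    writeBin(desc_here, con)
    page <- t(v$voxels[z, , ]) # row-major: x fastest within each row
    writeBin(encode_pixels(as.vector(page), dtype), con)
    offset <- as.integer(data_off + strip_bytes)
  }
  invisible(path)
}

read_le <- function(raw, off, size, n = 1L, what = "integer", signed = TRUE) {
  if (off + size * n - 1L > length(raw))
    stop("volume format error: truncated TIFF file", call. = FALSE)
  readBin(raw[off:(off + size * n - 1L)], what = what, n = n, size = size,
          endian = "little", signed = signed)
}

#' @rdname volume-io
#' @export
read_tiff_volume <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 8 || rawToChar(bytes[1:2]) != "II" ||
      read_le(bytes, 3L, 2L) != 42L)
    stop("volume format error: not a little-endian TIFF", call. = FALSE)
  ifd <- read_le(bytes, 5L, 4L)
  pages <- list()
  spacing <- 1; origin <- c(0, 0, 0)
  while (ifd != 0L) {
    n <- read_le(bytes, ifd + 1L, 2L)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + 12L * (i - 1L)
      tag <- read_le(bytes, e + 1L, 2L)
      type <- read_le(bytes, e + 3L, 2L)
      count <- read_le(bytes, e + 5L, 4L)
      val <- if (type == 3L) read_le(bytes, e + 9L, 2L)
             else read_le(bytes, e + 9L, 4L)
      tags[[as.character(tag)]] <- list(type = type, count = count, val = val)
    }
    need <- function(t) {
      x <- tags[[as.character(t)]]
      if (is.null(x)) stop("volume format error: missing TIFF tag ", t,
                           call. = FALSE)
      x$val
    }
    if (!is.null(tags[["259"]]) && tags[["259"]]$val != 1L)
      stop("volume format error: compressed TIFF not supported", call. = FALSE)
    nx <- need(256L); ny <- need(257L); bits <- need(258L)
    off <- need(273L); nbytes <- need(279L)
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]]$val
    if (nbytes != nx * ny * bits / 8)
      stop("volume format error: inconsistent strip size", call. = FALSE)
    if (fmt == 3L) {
      vals <- read_le(bytes, off + 1L, bits %/% 8L, nx * ny, what = "double")
    } else {
      size <- bits %/% 8L
      if (size == 1L) {
        if (off + nbytes > length(bytes))
          stop("volume format error: truncated TIFF file", call. = FALSE)
        vals <- as.integer(bytes[(off + 1L):(off + nbytes)])
      } else {
        vals <- read_le(bytes, off + 1L, size, nx * ny,
                        signed = (size == 4L))
        if (size == 2L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
      }
    }
    dsc <- tags[["270"]]
    if (!is.null(dsc) && dsc$count > 4L) {
      txt <- rawToChar(bytes[(dsc$val + 1L):(dsc$val + dsc$count - 1L)])
      meta <- tryCatch(jsonlite::fromJSON(sub("\\x00+$", "", txt)),
                       error = function(e) NULL)
      if (!is.null(meta$spacing_nm)) spacing <- meta$spacing_nm
      if (!is.null(meta$origin_nm)) origin <- meta$origin_nm
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nx, ny)) # back to [y, x]
    ifd <- read_le(bytes, ifd + 2L + 12L * n + 1L, 4L)
  }
  if (!length(pages)) stop("volume format error: empty TIFF", call. = FALSE)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(length(pages), ny, nx))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  if (all(arr == round(arr)) && max(abs(arr)) < 2^31) arr <- array(as.integer(arr), dim(arr))
  volume3d(arr, spacing = spacing, origin = origin)
}

MHD_TYPES <- c(uint8 = "MET_UCHAR", uint16 = "MET_USHORT", uint32 = "MET_UINT",
               float32 = "MET_FLOAT", float64 = "MET_DOUBLE")

#' @rdname volume-io
#' @export
write_mhd_volume <- function(v, path, dtype = "auto") {
  stopifnot(is_volume3d(v))
  if (dtype == "auto") dtype <- auto_dtype(v$voxels)
  if (!dtype %in% names(MHD_TYPES)) stop("unsupported dtype: ", dtype,
                                         call. = FALSE)
  d <- dim(v$voxels)
  raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", d[3], d[2], d[1]),
           paste("ElementSpacing =", v$spacing, v$spacing, v$spacing),
           paste("Offset =", v$origin[3], v$origin[2], v$origin[1]),
           paste("ElementType =", MHD_TYPES[[dtype]]),
           paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  x <- as.vector(aperm(v$voxels, c(3, 2, 1))) # x fastest on disk
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(encode_pixels(x, dtype), con)
  invisible(path)
}

#' @rdname volume-io
#' @export
read_mhd_volume <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  dims <- rev(as.integer(strsplit(get("DimSize"), "\\s+")[[1]])) # -> (z,y,x)
  sp <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])[1]
  org <- rev(as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]]))
  met <- get("ElementType")
  dtype <- names(MHD_TYPES)[match(met, MHD_TYPES)]
  if (is.na(dtype)) stop("volume format error: unsupported ElementType ", met,
                         call. = FALSE)
  raw_path <- file.path(dirname(path), get("ElementDataFile"))
  tp <- TIFF_TYPES[[dtype]]
  n <- prod(dims)
  sz <- file.info(raw_path)$size
  if (is.na(sz) || sz < n * tp$size)
    stop("volume format error: truncated or missing RAW file", call. = FALSE)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (tp$fmt == 3L) {
    vals <- readBin(con, "double", n = n, size = tp$size, endian = "little")
  } else if (tp$size == 1L) {
    vals <- as.integer(readBin(con, raw(), n = n))
  } else {
    vals <- readBin(con, "integer", n = n, size = tp$size, endian = "little",
                    signed = (tp$size == 4L))
    if (tp$size == 2L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
  }
  if (tp$fmt == 1L) vals <- as.integer(vals)
  arr <- aperm(array(vals, rev(dims)), c(3, 2, 1))
  volume3d(arr, spacing = sp, origin = org)
}

#' @rdname volume-io
#' @export
write_volume <- function(v, path, dtype = "auto") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = write_tiff_volume(v, path, dtype),
         mhd = write_mhd_volume(v, path, dtype),
         stop("volume format error: unsupported extension .", ext,
              call. = FALSE))
}

#' @rdname volume-io
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = read_tiff_volume(path),
         mhd = read_mhd_volume(path),
         stop("volume format error: unsupported extension .", ext,
              call. = FALSE))
}

#' Write an RGB image (0..255) as PNG
#'
#' Used for the histology-mimicking renderings.  Requires a PNG-capable
#' graphics device (standard in R builds); errors otherwise.
#'
#' @param rgb `h x w x 3` array, values 0..255.
#' @param path output file.
#' @export
write_png_image <- function(rgb, path) {
  if (!capabilities("png"))
    stop("this R build has no PNG device", call. = FALSE)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  grDevices::png(path, width = w, height = h)
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(rgb / 255), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(path)
}
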