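# Minimal baseline TIFF 6.0 codec (little-endian, uncompressed, grayscale,
# one strip per page). The pre-installed stack has no TIFF package for R, so
# the package carries its own reader/writer for the subset it needs:
# uint8/16/32 and float32/64 samples, multi-page, ImageDescription metadata.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, ImageDescription = 270L,
  StripOffsets = 273L, RowsPerStrip = 278L, StripByteCounts = 279L,
  SampleFormat = 339L
)

# type codes: 2 ASCII, 3 SHORT, 4 LONG
.tiff_entry <- function(tag, type, count, value) {
  list(tag = tag, type = type, count = count, value = value)
}

.tiff_pack_entries <- function(entries, con) {
  writeBin(length(entries), con, size = 2L, endian = "little")
  for (e in entries) {
    writeBin(e$tag, con, size = 2L, endian = "little")
    writeBin(e$type, con, size = 2L, endian = "little")
    writeBin(e$count, con, size = 4L, endian = "little")
    if (e$type == 3L && e$count == 1L) {
      writeBin(e$value, con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(e$value, con, size = 4L, endian = "little")
    }
  }
}

#' Write a multi-page grayscale TIFF
#'
#' Pages are written in the order of the third dimension of `pages`.
#' Integer-valued data that fits in 16 bits is stored as uint16 (lossless);
#' anything else is stored as IEEE float64 (lossless for doubles).
#'
#' @param pages numeric array (y, x, page).
#' @param path output file path.
#' @param description character scalar stored in the first page's
#'   ImageDescription tag (used for stack metadata).
#' @return `path`, invisibly.
#' @keywords internal
write_tiff_pages <- function(pages, path, description = "") {
  stopifnot(length(dim(pages)) == 3L)
  ny <- dim(pages)[1L]; nx <- dim(pages)[2L]; np <- dim(pages)[3L]
  vals <- as.vector(pages)
  is_u16 <- all(is.finite(vals)) && all(vals >= 0) && all(vals <= 65535) &&
    all(vals == floor(vals))
  bps <- if (is_u16) 16L else 64L
  fmt <- if (is_u16) 1L else 3L          # 1 = unsigned int, 3 = IEEE float
  bytes_pp <- as.integer(ny * nx * bps / 8L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2L, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")

  desc_raw <- c(charToRaw(enc2utf8(description)), as.raw(0L))
  data_start <- 8L
  desc_off <- data_start + np * bytes_pp
  ifd0_off <- desc_off + length(desc_raw)
  ifd0_off <- ifd0_off + (ifd0_off %% 2L)   # word-align
  n_entries <- function(p) if (p == 1L && nzchar(description)) 10L else 9L
  ifd_size <- function(p) 2L + 12L * n_entries(p) + 4L
  ifd_off <- integer(np)
  off <- ifd0_off
  for (p in seq_len(np)) { ifd_off[p] <- off; off <- off + ifd_size(p) }

  writeBin(ifd_off[1L], con, size = 4L, endian = "little")
  for (p in seq_len(np)) {
    # TIFF is row-major: row = y, column = x
    plane <- t(pages[, , p])              # (x, y) column-major == row-major (y, x)
    if (is_u16) {
      writeBin(as.integer(plane), con, size = 2L, endian = "little")
    } else {
      writeBin(as.double(plane), con, size = 8L, endian = "little")
    }
  }
  writeBin(desc_raw, con)
  if (seek(con) %% 2L == 1L) writeBin(as.raw(0L), con)

  for (p in seq_len(np)) {
    stopifnot(seek(con) == ifd_off[p])
    entries <- list(
      .tiff_entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, nx),
      .tiff_entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, ny),
      .tiff_entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bps),
      .tiff_entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      .tiff_entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L)
    )
    if (p == 1L && nzchar(description)) {
      entries <- c(entries, list(.tiff_entry(
        TIFF_TAGS[["ImageDescription"]], 2L, length(desc_raw), desc_off)))
    }
    entries <- c(entries, list(
      .tiff_entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L,
                  data_start + (p - 1L) * bytes_pp),
      .tiff_entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, ny),
      .tiff_entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, bytes_pp),
      .tiff_entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, fmt)
    ))
    # tags must be ascending
    entries <- entries[order(vapply(entries, `[[`, 0L, "tag"))]
    .tiff_pack_entries(entries, con)
    writeBin(if (p < np) ifd_off[p + 1L] else 0L, con,
             size = 4L, endian = "little")
  }
  invisible(path)
}

.read_u <- function(raw, off, n, size, endian) {
  readBin(raw[(off + 1L):(off + n * size)], "integer", n = n, size = size,
          endian = endian, signed = size >= 4L)
}

#' Read a multi-page grayscale TIFF written by this package (or any
#' uncompressed single-sample baseline TIFF)
#'
#' @param path file path.
#' @return list with `pages` (array y, x, page) and `description`
#'   (character, possibly empty).
#' @keywords internal
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (.read_u(raw, 2L, 1L, 2L, endian) != 42L)
    stop("not a TIFF file: ", path)
  ifd_off <- .read_u(raw, 4L, 1L, 4L, endian)
  pages <- list(); description <- ""

  while (ifd_off != 0L) {
    n_ent <- .read_u(raw, ifd_off, 1L, 2L, endian)
    tags <- list()
    for (i in seq_len(n_ent)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- .read_u(raw, e, 1L, 2L, endian)
      type <- .read_u(raw, e + 2L, 1L, 2L, endian)
      count <- .read_u(raw, e + 4L, 1L, 4L, endian)
      tsize <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
      nbytes <- tsize * count
      voff <- if (nbytes > 4L) .read_u(raw, e + 8L, 1L, 4L, endian) else e + 8L
      val <- switch(as.character(type),
        "2" = {
          b <- raw[(voff + 1L):(voff + count)]
          z <- which(b == as.raw(0L))
          if (length(z) > 0L) b <- b[seq_len(z[1L] - 1L)]
          rawToChar(b)
        },
        "3" = .read_u(raw, voff, count, 2L, endian),
        "4" = .read_u(raw, voff, count, 4L, endian),
        .read_u(raw, voff, count, tsize, endian))
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[id]])]]
      if (is.null(v)) default else v
    }
    if (!identical(g("Compression", 1L), 1L))
      stop("unsupported TIFF compression: ", g("Compression"))
    nx <- g("ImageWidth"); ny <- g("ImageLength")
    bps <- g("BitsPerSample"); fmt <- g("SampleFormat", 1L)
    offs <- g("StripOffsets"); cnts <- g("StripByteCounts")
    if (nzchar(g("ImageDescription", "")) && !nzchar(description))
      description <- g("ImageDescription")
    buf <- raw(sum(cnts)); pos <- 0L
    for (s in seq_along(offs)) {
      buf[(pos + 1L):(pos + cnts[s])] <- raw[(offs[s] + 1L):(offs[s] + cnts[s])]
      pos <- pos + cnts[s]
    }
    vals <- if (fmt == 3L) {
      readBin(buf, "double", n = nx * ny, size = bps / 8L, endian = endian)
    } else {
      readBin(buf, "integer", n = nx * ny, size = bps / 8L, endian = endian,
              signed = bps >= 32L)
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = nx, ncol = ny))
    ifd_off <- .read_u(raw, ifd_off + 2L + n_ent * 12L, 1L, 4L, endian)
  }
  arr <- array(0, dim = c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- pages[[p]]
  list(pages = arr, description = description)
}
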