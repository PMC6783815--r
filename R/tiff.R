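# Minimal baseline TIFF codec for grayscale multi-page stacks.
# Scope: uncompressed, single-sample pages; 8/16-bit unsigned integer or
# 32-bit float; strip layout; both byte orders on read, little-endian on
# write. Voxel spacing rides in XResolution/YResolution (pixels per unit,
# ResolutionUnit = none), so spacing = denominator / numerator.
# No pre-installed R package in this stack reads TIFF, hence the hand-rolled
# codec; anything fancier (compression, tiles, palettes) is out of scope.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_uint <- function(raw, off, size, endian) {
  # off is 0-based; returns double (values can exceed .Machine$integer.max)
  bytes <- as.integer(raw[(off + 1):(off + size)])
  if (endian == "big") bytes <- rev(bytes)
  sum(bytes * 256^(seq_len(size) - 1))
}

read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (read_uint(raw, 2, 2, endian) != 42)
    stop("not a TIFF file (bad magic number): ", path)

  pages <- list()
  ifd_off <- read_uint(raw, 4, 4, endian)
  while (ifd_off != 0) {
    n_entries <- read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- read_uint(raw, e, 2, endian)
      type <- read_uint(raw, e + 2, 2, endian)
      count <- read_uint(raw, e + 4, 4, endian)
      tsize <- TIFF_TYPE_SIZE[[as.character(type)]]
      if (is.null(tsize)) next
      nbytes <- tsize * count
      voff <- if (nbytes <= 4) e + 8 else read_uint(raw, e + 8, 4, endian)
      vals <- switch(as.character(type),
        `3` = vapply(seq_len(count) - 1,
                     function(k) read_uint(raw, voff + 2 * k, 2, endian), 0),
        `4` = vapply(seq_len(count) - 1,
                     function(k) read_uint(raw, voff + 4 * k, 4, endian), 0),
        `5` = vapply(seq_len(count) - 1, function(k) {
                num <- read_uint(raw, voff + 8 * k, 4, endian)
                den <- read_uint(raw, voff + 8 * k + 4, 4, endian)
                if (den == 0) NA_real_ else num / den
              }, 0),
        `1` = vapply(seq_len(count) - 1,
                     function(k) read_uint(raw, voff + k, 1, endian), 0),
        NULL)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    pages[[length(pages) + 1L]] <- tags
    ifd_off <- read_uint(raw, ifd_off + 2 + n_entries * 12, 4, endian)
  }
  if (!length(pages)) stop("TIFF contains no images: ", path)

  need <- function(tags, tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      default
    } else v
  }

  decode_page <- function(tags) {
    w <- need(tags, 256); h <- need(tags, 257)
    bits <- need(tags, 258, 1)
    if (need(tags, 259, 1) != 1) stop("unsupported TIFF: compressed data")
    if (need(tags, 277, 1) != 1) stop("unsupported TIFF: multi-sample pixels")
    fmt <- need(tags, 339, 1)
    offs <- need(tags, 273); cnts <- need(tags, 279)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    npx <- w * h
    vals <- if (fmt == 3 && bits == 32) {
      readBin(buf, "double", n = npx, size = 4, endian = endian)
    } else if (fmt == 1 && bits == 8) {
      as.numeric(readBin(buf, "integer", n = npx, size = 1, signed = FALSE,
                         endian = endian))
    } else if (fmt == 1 && bits == 16) {
      as.numeric(readBin(buf, "integer", n = npx, size = 2, signed = FALSE,
                         endian = endian))
    } else {
      stop(sprintf(
        "unsupported TIFF pixel type: %d-bit, sample format %d", bits, fmt))
    }
    list(w = w, h = h, m = matrix(vals, nrow = w, ncol = h))  # col-per-row
  }

  dec <- lapply(pages, decode_page)
  ws <- vapply(dec, `[[`, 0, "w"); hs <- vapply(dec, `[[`, 0, "h")
  if (length(unique(ws)) != 1L || length(unique(hs)) != 1L)
    stop("non-uniform page shapes in TIFF stack: ", path)
  nz <- length(dec); ny <- hs[1]; nx <- ws[1]
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- t(dec[[z]]$m)

  xres <- pages[[1]][["282"]]
  spacing <- if (!is.null(xres) && is.finite(xres[1]) && xres[1] > 0)
    1 / xres[1] else NA_real_
  list(data = arr, spacing = spacing)
}

# encode a double as an unsigned rational (num, den)
spacing_to_rational <- function(spacing) {
  num <- 1e8
  den <- round(spacing * num)
  if (den > 4294967294 || den < 1) {
    num <- max(1, min(4294967294, round(4294967294 / spacing / 2)))
    den <- max(1, round(spacing * num))
  }
  c(num, den)
}

write_tiff_stack <- function(arr, path, spacing = 1.0, type = NULL) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  d <- dim(arr); nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (is.null(type)) {
    type <- if (is.logical(arr)) "uint8"
    else if (all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 255 &&
             all(is.finite(arr))) "uint8"
    else if (all(arr == round(arr)) && min(arr) >= 0 && max(arr) <= 65535 &&
             all(is.finite(arr))) "uint16"
    else "float32"
  }
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (type == "float32") 3L else 1L
  bpp <- bits / 8L
  page_bytes <- ny * nx * bpp
  rat <- spacing_to_rational(spacing)

  n_entries <- 13L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  ext_bytes <- 16L  # two rationals
  block <- ifd_bytes + ext_bytes + page_bytes
  block <- block + (block %% 2L)  # keep offsets even

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("II", con, eos = NULL); wb(42, 2); wb(8, 4)

  u32 <- function(x) {  # split a double into two u16 words, little-endian
    x <- as.numeric(x)
    lo <- x %% 65536; hi <- (x - lo) / 65536
    wb(lo, 2); wb(hi, 2)
  }
  entry <- function(tag, type, count, value, is_offset = FALSE) {
    wb(tag, 2); wb(type, 2); u32(count)
    if (type == 3 && !is_offset) { wb(value, 2); wb(0, 2) } else u32(value)
  }

  for (z in seq_len(nz)) {
    base <- 8 + (z - 1) * block
    rat_off <- base + ifd_bytes
    data_off <- rat_off + ext_bytes
    next_off <- if (z < nz) 8 + z * block else 0

    wb(n_entries, 2)
    entry(256, 4, 1, nx)               # ImageWidth
    entry(257, 4, 1, ny)               # ImageLength
    entry(258, 3, 1, bits)             # BitsPerSample
    entry(259, 3, 1, 1)                # Compression: none
    entry(262, 3, 1, 1)                # Photometric: BlackIsZero
    entry(273, 4, 1, data_off)         # StripOffsets
    entry(277, 3, 1, 1)                # SamplesPerPixel
    entry(278, 4, 1, ny)               # RowsPerStrip
    entry(279, 4, 1, page_bytes)       # StripByteCounts
    entry(282, 5, 1, rat_off)          # XResolution
    entry(283, 5, 1, rat_off + 8)      # YResolution
    entry(296, 3, 1, 1)                # ResolutionUnit: none
    entry(339, 3, 1, fmt)              # SampleFormat
    u32(next_off)

    u32(rat[1]); u32(rat[2])           # XResolution = num/den px per unit
    u32(rat[1]); u32(rat[2])

    page <- t(arr[z, , , drop = TRUE])  # row-major: x fastest
    vals <- as.vector(page)
    if (type == "float32") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else if (type == "uint16") {
      v <- as.numeric(vals)
      lo <- v %% 256; hi <- (v - lo) / 256
      iv <- as.integer(rbind(lo, hi))
      writeBin(as.raw(iv), con)
    } else {
      v <- as.numeric(vals)
      if (is.logical(arr)) v <- v * 255
      writeBin(as.raw(as.integer(v)), con)
    }
    pad <- block - (ifd_bytes + ext_bytes + page_bytes)
    if (pad > 0) writeBin(raw(pad), con)
  }
  invisible(path)
}
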