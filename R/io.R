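## Multi-page TIFF input/output for real-valued multi-channel stacks.
##
## Stacks are written as one grayscale page per (z, channel) plane, channel
## fastest, in IEEE float32 (or the original unsigned integer dtype), with the
## acquisition metadata embedded as a JSON block in the ImageDescription tag of
## the first page. Uncompressed little-endian TIFF only: the point is a
## lossless, self-describing container for Z-scored (hence signed, unbounded)
## intensities, which rules out the usual [0,1]-scaled integer storage.

TAG <- list(width = 256L, height = 257L, bits = 258L, compression = 259L,
            photometric = 262L, description = 270L, strip_offsets = 273L,
            samples_per_pixel = 277L, rows_per_strip = 278L,
            strip_bytes = 279L, sample_format = 339L)

# Round doubles to their nearest float32 representation.
quantize_float32 <- function(x) {
  d <- dim(x)
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               "numeric", length(x), size = 4L, endian = "little")
  dim(q) <- d
  q
}

dtype_bytes <- function(dtype) switch(dtype, float32 = 4L, uint16 = 2L,
                                      uint8 = 1L, stop("bad dtype"))
dtype_format <- function(dtype) if (dtype == "float32") 3L else 1L

w16 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                 endian = "little")
w32 <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                 endian = "little")

write_ifd_entry <- function(con, tag, type, count, value) {
  w16(con, tag); w16(con, type); w32(con, count)
  if (type == 3L && count == 1L) { # SHORT packed into the first 2 bytes
    w16(con, value); w16(con, 0L)
  } else {
    w32(con, value)
  }
}

write_plane_data <- function(con, plane, dtype) {
  v <- as.vector(t(plane)) # row-major as TIFF expects
  if (dtype == "float32") {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  } else if (dtype == "uint16") {
    iv <- as.integer(round(v))
    if (any(iv < 0L | iv > 65535L)) stop("values out of uint16 range")
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L
    writeBin(iv, con, size = 2L, endian = "little")
  } else {
    iv <- as.integer(round(v))
    if (any(iv < 0L | iv > 255L)) stop("values out of uint8 range")
    writeBin(iv, con, size = 1L)
  }
}

#' Write a multi-channel stack to a multi-page TIFF
#'
#' One grayscale page is emitted per (z, channel) plane, channel-fastest, with
#' stack shape, pixel sizes and channel names stored as JSON in the
#' ImageDescription tag so that [read_stack()] recovers the full
#' `(z, y, x, c)` volume and its metadata. Storage is lossless for the chosen
#' sample format: voxels are rounded to float32 (the default), or written
#' verbatim for integer dtypes declared in `meta$dtype`.
#'
#' @param stack Numeric array `(z, y, x, c)` (3-D input is treated as one
#'   channel); must be finite.
#' @param meta A [stack_meta()] object; `meta$dtype` selects the on-disk
#'   sample format.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, meta, path) {
  stack <- check_stack(stack, meta)
  d <- dim(stack)
  z <- d[1]; h <- d[2]; w <- d[3]; nc <- d[4]
  dtype <- meta$dtype
  bps <- dtype_bytes(dtype) * 8L

  desc <- jsonlite::toJSON(list(
    fibrestain = 1L, shape = d, pixel_size_xy = meta$pixel_size_xy,
    z_step = meta$z_step, channel_names = meta$channel_names,
    dtype = dtype), auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  n_pages <- z * nc
  plane_bytes <- h * w * dtype_bytes(dtype)
  n_entries <- c(10L, rep(9L, n_pages - 1L)) # description on page 1 only
  ifd_sizes <- 2L + 12L * n_entries + 4L

  desc_ofs <- 8L
  data_ofs <- desc_ofs + length(desc_raw) + (seq_len(n_pages) - 1L) * plane_bytes
  ifd0 <- desc_ofs + length(desc_raw) + n_pages * plane_bytes
  ifd_ofs <- ifd0 + cumsum(c(0L, ifd_sizes[-n_pages]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); w16(con, 42L); w32(con, ifd_ofs[1])
  writeBin(desc_raw, con)
  p <- 0L
  for (zi in seq_len(z)) for (ci in seq_len(nc)) {
    p <- p + 1L
    write_plane_data(con, stack[zi, , , ci], dtype)
  }
  for (p in seq_len(n_pages)) {
    w16(con, n_entries[p])
    write_ifd_entry(con, TAG$width, 4L, 1L, w)
    write_ifd_entry(con, TAG$height, 4L, 1L, h)
    write_ifd_entry(con, TAG$bits, 3L, 1L, bps)
    write_ifd_entry(con, TAG$compression, 3L, 1L, 1L)
    write_ifd_entry(con, TAG$photometric, 3L, 1L, 1L)
    if (p == 1L)
      write_ifd_entry(con, TAG$description, 2L, length(desc_raw), desc_ofs)
    write_ifd_entry(con, TAG$strip_offsets, 4L, 1L, data_ofs[p])
    write_ifd_entry(con, TAG$samples_per_pixel, 3L, 1L, 1L)
    write_ifd_entry(con, TAG$strip_bytes, 4L, 1L, plane_bytes)
    write_ifd_entry(con, TAG$sample_format, 3L, 1L, dtype_format(dtype))
    w32(con, if (p < n_pages) ifd_ofs[p + 1L] else 0L)
  }
  invisible(path)
}

read_u <- function(raw, ofs, size) { # little-endian unsigned int from raw
  b <- as.integer(raw[ofs + seq_len(size)])
  sum(b * 256^(seq_len(size) - 1L))
}

read_ifd_entries <- function(raw, ofs) {
  n <- read_u(raw, ofs, 2L)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e <- ofs + 2L + (i - 1L) * 12L
    tag <- read_u(raw, e, 2L)
    type <- read_u(raw, e + 2L, 2L)
    count <- read_u(raw, e + 4L, 4L)
    tsz <- c(1L, 1L, 2L, 4L, 8L)[min(type, 5L)]
    total <- tsz * count
    vofs <- if (total <= 4L) e + 8L else read_u(raw, e + 8L, 4L)
    val <- if (type == 2L) {
      rawToChar(raw[vofs + seq_len(max(count - 1L, 0L))])
    } else if (type %in% c(3L, 4L)) {
      vapply(seq_len(count) - 1L, function(k) read_u(raw, vofs + k * tsz, tsz),
             numeric(1))
    } else NULL
    entries[[i]] <- list(tag = tag, value = val)
  }
  list(entries = entries, next_ofs = read_u(raw, ofs + 2L + n * 12L, 4L))
}

tag_value <- function(entries, tag, default = NULL) {
  for (e in entries) if (e$tag == tag) return(e$value)
  default
}

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II" || read_u(raw, 2L, 2L) != 42L)
    stop("not a little-endian TIFF file: ", path)
  ofs <- read_u(raw, 4L, 4L)
  pages <- list(); desc <- NULL
  while (ofs != 0L) {
    ifd <- read_ifd_entries(raw, ofs)
    en <- ifd$entries
    w <- tag_value(en, TAG$width); h <- tag_value(en, TAG$height)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    if (tag_value(en, TAG$compression, 1L) != 1L)
      stop("compressed TIFF not supported")
    if (tag_value(en, TAG$samples_per_pixel, 1L) != 1L)
      stop("only single-sample (grayscale) pages supported")
    bits <- tag_value(en, TAG$bits, 8L)[1]
    fmt <- tag_value(en, TAG$sample_format, 1L)[1]
    so <- tag_value(en, TAG$strip_offsets)
    sb <- tag_value(en, TAG$strip_bytes)
    if (is.null(desc)) desc <- tag_value(en, TAG$description)
    buf <- do.call(c, lapply(seq_along(so), function(i)
      raw[so[i] + seq_len(sb[i])]))
    n <- w * h
    v <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "numeric", n, size = 4L, endian = "little")
    } else if (fmt == 1L && bits == 16L) {
      readBin(buf, "integer", n, size = 2L, signed = FALSE, endian = "little")
    } else if (fmt == 1L && bits == 8L) {
      as.integer(buf[seq_len(n)])
    } else stop(sprintf("unsupported sample format (bits=%d, fmt=%d)", bits, fmt))
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), nrow = h, ncol = w,
                                          byrow = TRUE)
    ofs <- ifd$next_ofs
  }
  list(pages = pages, description = desc)
}

#' Read a multi-channel stack from a multi-page TIFF
#'
#' Voxel values are preserved bit-exactly as stored. Metadata resolution
#' order: the embedded JSON description written by [write_stack()], then
#' `meta_override`, then [stack_meta()] defaults (single channel). Pages are
#' assembled channel-fastest into the fixed `(z, y, x, c)` axis order.
#'
#' @param path TIFF file path.
#' @param meta_override Optional [stack_meta()] used when the file carries no
#'   embedded metadata; its channel count must divide the page count.
#' @return `list(stack = array(z, y, x, c), meta = stack_meta)`.
#' @export
read_stack <- function(path, meta_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tf <- read_tiff_pages(path)
  pages <- tf$pages
  if (length(pages) == 0L) stop("TIFF contains no pages")
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("inconsistent page shapes")
  h <- shapes[1, 1]; w <- shapes[2, 1]

  info <- NULL
  if (!is.null(tf$description) && grepl("\"fibrestain\"", tf$description,
                                        fixed = TRUE)) {
    info <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  }
  if (!is.null(info)) {
    meta <- stack_meta(info$pixel_size_xy, info$z_step, info$channel_names,
                       info$dtype)
    nc <- length(meta$channel_names)
  } else if (!is.null(meta_override)) {
    meta <- meta_override
    nc <- length(meta$channel_names)
  } else {
    meta <- stack_meta(channel_names = "ch1")
    nc <- 1L
  }
  if (length(pages) %% nc != 0L)
    stop(sprintf("page count %d not divisible by declared channel count %d",
                 length(pages), nc))
  z <- length(pages) %/% nc
  stack <- array(0, dim = c(z, h, w, nc))
  p <- 0L
  for (zi in seq_len(z)) for (ci in seq_len(nc)) {
    p <- p + 1L
    stack[zi, , , ci] <- pages[[p]]
  }
  list(stack = stack, meta = meta)
}

#' Write a tabular report as CSV
#'
#' @param df Data frame (one row per segment, slice or metric).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
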