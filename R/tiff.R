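# Minimal multi-page TIFF IO (uncompressed, 16-bit grayscale,
# little-endian). No R TIFF package is assumed; only the baseline subset
# needed for t-series round-trips is supported.

u16_to_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}

raw_to_u16 <- function(r) {
  m <- matrix(as.integer(r), nrow = 2)
  m[1, ] + 256L * m[2, ]
}

raw_u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (count 1 only here)
  val <- if (type == 3) c(raw_u32(value)[1:2], as.raw(c(0, 0))) else raw_u32(value)
  c(raw_u32(tag)[1:2], raw_u32(type)[1:2], raw_u32(count), val)
}

#' Write and read multi-page TIFF t-series
#'
#' `write_tseries` stores an `sls_movie` (or ny x nx x frames array) as an
#' uncompressed 16-bit grayscale multi-page TIFF plus a JSON metadata
#' sidecar (`<path>.json`: dwell, frame period, pixel size);
#' `read_tseries` reverses it losslessly. Only this baseline TIFF subset
#' is supported; anything else is a parse error naming the page.
#'
#' @param movie an `sls_movie` or numeric array with values in
#'   \[0, 65535\].
#' @param path output .tif path.
#' @return `write_tseries`: the path, invisibly. `read_tseries`: an
#'   `sls_movie` (metadata NA when no sidecar is present).
#' @export
write_tseries <- function(movie, path) {
  dat <- if (inherits(movie, "sls_movie")) movie$data else movie
  stopifnot(length(dim(dat)) == 3)
  if (min(dat) < 0 || max(dat) > 65535) stopf("values outside the 16-bit range")
  ny <- dim(dat)[1]; nx <- dim(dat)[2]; nf <- dim(dat)[3]
  page_bytes <- ny * nx * 2
  ifd_size <- 2 + 10 * 12 + 4
  data_off <- 8 + (seq_len(nf) - 1) * page_bytes
  ifd0 <- 8 + nf * page_bytes
  ifd_off <- ifd0 + (seq_len(nf) - 1) * ifd_size
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2A, 0x00)), con)
  writeBin(raw_u32(ifd0), con)
  for (f in seq_len(nf))
    writeBin(u16_to_raw(as.vector(t(dat[, , f]))), con)
  for (f in seq_len(nf)) {
    entries <- c(
      tiff_entry(256, 4, 1, nx),            # ImageWidth
      tiff_entry(257, 4, 1, ny),            # ImageLength
      tiff_entry(258, 3, 1, 16),            # BitsPerSample
      tiff_entry(259, 3, 1, 1),             # Compression = none
      tiff_entry(262, 3, 1, 1),             # Photometric = BlackIsZero
      tiff_entry(273, 4, 1, data_off[f]),   # StripOffsets
      tiff_entry(277, 3, 1, 1),             # SamplesPerPixel
      tiff_entry(278, 4, 1, ny),            # RowsPerStrip
      tiff_entry(279, 4, 1, page_bytes),    # StripByteCounts
      tiff_entry(339, 3, 1, 1))             # SampleFormat = unsigned
    nxt <- if (f < nf) ifd_off[f + 1] else 0
    writeBin(c(raw_u32(10)[1:2], entries, raw_u32(nxt)), con)
  }
  meta <- if (inherits(movie, "sls_movie"))
    list(dwell = movie$dwell, frame_period = movie$frame_period,
         pixel_size = movie$pixel_size) else NULL
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_tseries
#' @export
read_tseries <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8 || raw_all[1] != 0x49 || raw_all[2] != 0x49)
    stopf("not a little-endian TIFF: %s", path)
  get_u16 <- function(off) as.integer(raw_all[off + 1]) +
    256L * as.integer(raw_all[off + 2])
  get_u32 <- function(off) as.numeric(raw_all[off + 1]) +
    256 * as.numeric(raw_all[off + 2]) + 65536 * as.numeric(raw_all[off + 3]) +
    16777216 * as.numeric(raw_all[off + 4])
  if (get_u16(2) != 42) stopf("bad TIFF magic in %s", path)
  off <- get_u32(4)
  frames <- list()
  page <- 0L
  shape <- NULL
  while (off != 0) {
    page <- page + 1L
    if (off + 2 > length(raw_all))
      stopf("truncated TIFF at page %d (IFD offset beyond file)", page)
    n_ent <- get_u16(off)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- off + 2 + (e - 1) * 12
      tag <- get_u16(base)
      type <- get_u16(base + 2)
      count <- get_u32(base + 4)
      val <- if (type == 3) get_u16(base + 8) else get_u32(base + 8)
      if (count > 1) val <- list(offset = get_u32(base + 8), count = count,
                                 type = type)
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags)))
      stopf("page %d: missing required TIFF tags", page)
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1)
      stopf("page %d: compressed TIFF not supported", page)
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16)
      stopf("page %d: only 16-bit samples supported", page)
    nx <- tags[["256"]]; ny <- tags[["257"]]
    read_longs <- function(tv) {
      if (!is.list(tv)) return(tv)
      vapply(seq_len(tv$count), function(i)
        if (tv$type == 3) get_u16(tv$offset + (i - 1) * 2)
        else get_u32(tv$offset + (i - 1) * 4), numeric(1))
    }
    offs <- read_longs(tags[["273"]])
    cnts <- read_longs(tags[["279"]])
    if (any(offs + cnts > length(raw_all)))
      stopf("truncated TIFF at page %d (strip beyond end of file)", page)
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw_all[(offs[i] + 1):(offs[i] + cnts[i])]))
    v <- raw_to_u16(bytes)
    if (length(v) != nx * ny)
      stopf("page %d: strip size does not match %dx%d image", page, ny, nx)
    if (is.null(shape)) shape <- c(ny, nx)
    if (shape[1] != ny || shape[2] != nx)
      stopf("page %d: frame shape %dx%d differs from first page %dx%d",
            page, ny, nx, shape[1], shape[2])
    frames[[page]] <- t(matrix(v, nx, ny))
    off <- get_u32(off + 2 + n_ent * 12)
  }
  if (!page) stopf("TIFF contains no pages: %s", path)
  dat <- array(unlist(frames), dim = c(shape[1], shape[2], page))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else
      list(dwell = NA_real_, frame_period = NA_real_, pixel_size = NA_real_)
  structure(list(data = dat, dwell = meta$dwell,
                 frame_period = meta$frame_period,
                 pixel_size = meta$pixel_size,
                 fs = if (is.na(meta$frame_period)) NA_real_ else
                   1 / meta$frame_period),
            class = "sls_movie")
}

#' Write an SNR map as a 32-bit float TIFF-like flat file
#'
#' SNR maps are written as plain CSV matrices for portability (one row per
#' image row); the companion JSON stores the interval.
#'
#' @param map an `sls_snr_map`.
#' @param path output .csv path.
#' @return the path, invisibly.
#' @export
write_snr_map <- function(map, path) {
  utils::write.table(map$snr, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(interval = map$interval), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
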