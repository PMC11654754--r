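# Minimal multi-page 32-bit-float TIFF writer/reader (little-endian,
# uncompressed, one strip per page). No TIFF-capable package exists in the
# deployment environment, so the subset needed for round-tripping simulation
# arrays is implemented here; readers like tifffile/ImageJ open these files.

write_tiff_f32 <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  n <- length(pages)
  dims <- lapply(pages, dim)
  sizes <- vapply(dims, function(d) d[1L] * d[2L] * 4L, 0)
  # layout: 8-byte header | page data ... | IFDs ...
  data_off <- 8 + cumsum(c(0, sizes[-n]))
  ifd_bytes <- 2 + 10 * 12 + 4
  ifd_off <- 8 + sum(sizes) + (seq_len(n) - 1L) * ifd_bytes
  writeBin(charToRaw("II"), con)
  w2(42); w4(ifd_off[1L])
  for (p in pages) writeBin(as.vector(t(p)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3) { w2(value); w2(0) } else w4(value)
  }
  for (k in seq_len(n)) {
    h <- dims[[k]][1L]; w <- dims[[k]][2L]
    w2(10)
    entry(256, 4, 1, w)            # ImageWidth
    entry(257, 4, 1, h)            # ImageLength
    entry(258, 3, 1, 32)           # BitsPerSample
    entry(259, 3, 1, 1)            # Compression: none
    entry(262, 3, 1, 1)            # Photometric: BlackIsZero
    entry(273, 4, 1, data_off[k])  # StripOffsets
    entry(277, 3, 1, 1)            # SamplesPerPixel
    entry(278, 4, 1, h)            # RowsPerStrip
    entry(279, 4, 1, sizes[k])     # StripByteCounts
    entry(339, 3, 1, 3)            # SampleFormat: IEEE float
    w4(if (k < n) ifd_off[k + 1L] else 0)
  }
  invisible(path)
}

read_tiff_f32 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  rd <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = size == 4)
  }
  if (rawToChar(raw[1:2]) != "II" || rd(2, 2) != 42L) {
    tb_stop("not a little-endian TIFF: ", path)
  }
  off <- rd(4, 4)
  pages <- list()
  while (off != 0) {
    nent <- rd(off, 2)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- off + 2 + (e - 1) * 12
      tag <- rd(base, 2); type <- rd(base + 2, 2); count <- rd(base + 4, 4)
      val <- if (type == 3) rd(base + 8, 2) else rd(base + 8, 4)
      if (count > 1L) {  # value is an offset to an array
        ptr <- rd(base + 8, 4)
        val <- rd(ptr, if (type == 3) 2 else 4, count)
      }
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    if (is.null(w) || is.null(h)) tb_stop("malformed TIFF IFD")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
      tb_stop("compressed TIFF not supported")
    }
    offs <- tags[["273"]]; counts <- tags[["279"]] %||% (w * h * 4)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      vals <- c(vals, readBin(raw[(offs[s] + 1):(offs[s] + counts[min(s, length(counts))])],
                              "numeric", n = counts[min(s, length(counts))] / 4,
                              size = 4, endian = "little"))
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    off <- rd(off + 2 + nent * 12, 4)
  }
  pages
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a projection stack or reconstruction volume to disk
#'
#' Data go to a multi-page 32-bit-float TIFF; geometry, coordinate system,
#' exposure, and seeds go to a JSON sidecar next to it. The round trip is
#' bit-exact for float32 data and lossless for metadata.
#'
#' @param obj a `projection_stack` or `recon_volume`.
#' @param path output TIFF path (`.tif`); the sidecar takes the same stem
#'   with `.json`.
#' @export
write_stack <- function(obj, path) {
  arr <- if (inherits(obj, "projection_stack")) obj$images else
    if (inherits(obj, "recon_volume")) obj$slices else
      tb_stop("write_stack supports projection_stack and recon_volume")
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
  write_tiff_f32(pages, path)
  meta <- unclass(obj)
  meta$images <- NULL; meta$slices <- NULL
  meta$geometry <- unclass(meta$geometry)
  meta$.class <- class(obj)[1L]
  meta$.format_version <- 1L
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    tb_stop("missing sidecar: expected metadata file '", sc, "' next to '",
            path, "'")
  }
  meta <- jsonlite::fromJSON(sc, simplifyVector = TRUE)
  if (!identical(meta$.format_version, 1L)) {
    warning("sidecar format version ", meta$.format_version,
            " differs from 1; attempting to read anyway")
  }
  pages <- read_tiff_f32(path)
  arr <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  cls <- meta$.class
  meta$.class <- NULL; meta$.format_version <- NULL
  geom <- make_geometry(meta$geometry[
    setdiff(names(meta$geometry), character(0))])
  if (cls == "projection_stack") {
    obj <- meta
    obj$images <- arr
    obj$geometry <- geom
    class(obj) <- "projection_stack"
  } else {
    obj <- meta
    obj$slices <- arr
    obj$geometry <- geom
    class(obj) <- "recon_volume"
  }
  obj
}
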