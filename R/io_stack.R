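# Stack writers/readers: multipage 16-bit TIFF (via the tiff package),
# single-HDU FITS, and a flat little-endian raw dump with a YAML header.
# One image file per channel plus one YAML metadata sidecar per stack.
#
# FITS support is written here directly (no FITS package is available to
# R in this toolchain): images are stored as BITPIX=16 with the standard
# BZERO=32768 convention for unsigned 16-bit data, one 3-D primary HDU
# per channel, 2880-byte header and data blocks.

.fits_card <- function(key, value, comment = "") {
  if (is.logical(value)) value <- if (value) "T" else "F"
  card <- sprintf("%-8s= %20s / %-47s", key, format(value), comment)
  substr(card, 1, 80)
}

.fits_write <- function(img3d, path) {
  dims <- dim(img3d)
  cards <- c(
    .fits_card("SIMPLE", TRUE, "conforms to FITS standard"),
    .fits_card("BITPIX", 16L, "16-bit signed with BZERO offset"),
    .fits_card("NAXIS", 3L, "image cube"),
    .fits_card("NAXIS1", dims[2], "width px"),
    .fits_card("NAXIS2", dims[1], "height px"),
    .fits_card("NAXIS3", dims[3], "z planes"),
    .fits_card("BZERO", 32768L, "unsigned 16-bit convention"),
    .fits_card("BSCALE", 1L, ""),
    sprintf("%-80s", "END")
  )
  header <- paste0(paste(cards, collapse = ""),
                   strrep(" ", (2880 - (length(cards) * 80) %% 2880) %% 2880))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  # FITS axis order: NAXIS1 fastest -> write row by row, plane by plane
  vals <- as.integer(img3d) - 32768L
  perm <- aperm(array(vals, dims), c(2, 1, 3)) # make width fastest
  writeBin(as.integer(perm), con, size = 2, endian = "big")
  nbytes <- length(vals) * 2
  pad <- (2880 - nbytes %% 2880) %% 2880
  if (pad > 0) writeBin(raw(pad), con)
  invisible(path)
}

.fits_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  keys <- list()
  repeat {
    block <- readChar(con, 2880, useBytes = TRUE)
    if (nchar(block) < 2880) stop("truncated FITS header: ", path)
    cards <- substring(block, seq(1, 2880, 80), seq(80, 2880, 80))
    for (card in cards) {
      key <- trimws(substr(card, 1, 8))
      if (key == "END") break
      if (grepl("=", substr(card, 9, 10))) {
        keys[[key]] <- trimws(strsplit(substr(card, 11, 80), "/")[[1]][1])
      }
    }
    if (any(trimws(substr(cards, 1, 8)) == "END")) break
  }
  w <- as.integer(keys$NAXIS1); h <- as.integer(keys$NAXIS2)
  np <- if (!is.null(keys$NAXIS3)) as.integer(keys$NAXIS3) else 1L
  bzero <- if (!is.null(keys$BZERO)) as.numeric(keys$BZERO) else 0
  n <- w * h * np
  vals <- readBin(con, "integer", n = n, size = 2, endian = "big") + bzero
  aperm(array(as.integer(vals), c(w, h, np)), c(2, 1, 3))
}

.raw_write <- function(img3d, path) {
  dims <- dim(img3d)
  hdr <- sub("\\.raw$", ".raw.yml", path)
  yaml::write_yaml(list(dtype = "uint16", endian = "little",
                        height_px = dims[1], width_px = dims[2],
                        n_planes = dims[3],
                        order = "plane-major, row-major within plane"),
                   hdr)
  vals <- as.integer(img3d)
  vals <- ifelse(vals > 32767L, vals - 65536L, vals) # reinterpret as int16
  perm <- aperm(array(vals, dims), c(2, 1, 3))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(perm), con, size = 2, endian = "little")
  invisible(path)
}

.raw_read <- function(path) {
  hdr <- yaml::read_yaml(sub("\\.raw$", ".raw.yml", path))
  n <- hdr$height_px * hdr$width_px * hdr$n_planes
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "integer", n = n, size = 2, endian = "little",
                  signed = TRUE)
  vals <- ifelse(vals < 0L, vals + 65536L, vals)
  aperm(array(as.integer(vals), c(hdr$width_px, hdr$height_px,
                                  hdr$n_planes)), c(2, 1, 3))
}

.tiff_write <- function(img3d, path) {
  pages <- lapply(seq_len(dim(img3d)[3]), function(p) {
    img3d[, , p] / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

.tiff_read <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0L, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                           length(pages)))
  for (p in seq_along(pages)) out[, , p] <- as.integer(pages[[p]])
  out
}

#' Write an acquired stack to disk
#'
#' Emits one image file per channel — multipage along z, 16-bit unsigned —
#' named by the stack filename convention (see [him_filename()]), plus a
#' single YAML metadata sidecar `<base>_meta.yml` for the whole stack.
#'
#' @param stack Integer array `height x width x planes x channels` with
#'   values in `[0, 65535]`.
#' @param dir Output directory (created if needed).
#' @param metadata A [stack_metadata()] object; supplies scan/probe/ROI for
#'   the filenames.
#' @param format "tiff", "fits" or "raw".
#' @return Character vector of written image file paths (sidecar excluded),
#'   invisibly.
#' @export
write_stack <- function(stack, dir, metadata, format = "tiff") {
  stopifnot(inherits(metadata, "StackMetadata"))
  if (length(dim(stack)) != 4 || dim(stack)[3] == 0) {
    stop("write_stack: stack must be a nonempty 4-D array (h, w, planes, channels)")
  }
  ext <- switch(format, tiff = "tif", fits = "fits", raw = "raw",
                stop("unsupported format: ", format))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_c <- dim(stack)[4]
  files <- character(n_c)
  for (ch in seq_len(n_c)) {
    fname <- him_filename(metadata$cycle, metadata$probe,
                          metadata$roi_id, ch - 1L, ext)
    path <- file.path(dir, fname)
    img3d <- stack[, , , ch, drop = FALSE]
    dim(img3d) <- dim(stack)[1:3]
    switch(format,
           tiff = .tiff_write(img3d, path),
           fits = .fits_write(img3d, path),
           raw = .raw_write(img3d, path))
    files[ch] <- path
  }
  base <- sub("_ch[0-9]{2}\\.[A-Za-z0-9]+$", "", basename(files[1]))
  sidecar <- file.path(dir, paste0(base, "_meta.yml"))
  yaml::write_yaml(unclass(metadata), sidecar)
  invisible(files)
}

#' Read one channel file of a saved stack
#'
#' @param path Image file written by [write_stack()].
#' @param format "tiff", "fits" or "raw"; inferred from the extension by
#'   default.
#' @return Integer array `height x width x planes`.
#' @export
read_stack_channel <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tif = , tiff = "tiff", fits = "fits", raw = "raw",
                     stop("cannot infer format of ", path))
  }
  switch(format,
         tiff = .tiff_read(path),
         fits = .fits_read(path),
         raw = .raw_read(path),
         stop("unsupported format: ", format))
}

#' Read a stack metadata sidecar
#'
#' @param path The `<base>_meta.yml` file.
#' @return The metadata as a `StackMetadata` list.
#' @export
read_stack_metadata <- function(path) {
  md <- yaml::read_yaml(path)
  class(md) <- "StackMetadata"
  md
}
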