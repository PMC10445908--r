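# ROI list management and mosaic planning.
#
# ROIs are named stage positions revisited every cycle. Mosaics are
# snake-ordered (boustrophedon) tilings: rows are visited top to bottom
# (increasing y), alternating direction, starting at the top-left tile
# moving rightward, which keeps consecutive tiles one pitch apart and
# minimizes stage travel.

#' Construct an ROI list
#'
#' @param x_um,y_um Stage coordinates (µm).
#' @param z_um Optional axial positions (µm); NA where undefined.
#' @param ids Optional ids; default 3-digit zero-padded ordinals
#'   ("001", "002", ...) in order.
#' @param travel_um Stage travel limit for validation (µm, symmetric).
#' @return Data frame of class `roi_list`: id, x_um, y_um, z_um.
#' @export
roi_list <- function(x_um, y_um, z_um = NULL, ids = NULL,
                     travel_um = 10000) {
  n <- length(x_um)
  stopifnot(length(y_um) == n)
  if (is.null(z_um)) z_um <- rep(NA_real_, n)
  if (is.null(ids)) ids <- sprintf("%03d", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate ROI id: ", ids[duplicated(ids)][1])
  }
  if (n > 0 && (max(abs(x_um)) > travel_um || max(abs(y_um)) > travel_um)) {
    stop("ROI coordinates outside stage travel of +/- ", travel_um, " um")
  }
  structure(data.frame(id = ids, x_um = as.numeric(x_um),
                       y_um = as.numeric(y_um), z_um = as.numeric(z_um),
                       stringsAsFactors = FALSE),
            class = c("roi_list", "data.frame"))
}

# Snake visit order over an n_rows x n_cols grid: row-major, direction
# alternating per row, starting top-left moving rightward. Returns a matrix
# with columns (row, col), one line per tile in visit order.
snake_order <- function(n_rows, n_cols) {
  out <- matrix(0L, nrow = n_rows * n_cols, ncol = 2)
  k <- 1L
  for (r in seq_len(n_rows)) {
    cols <- if (r %% 2 == 1) seq_len(n_cols) else rev(seq_len(n_cols))
    for (cc in cols) {
      out[k, ] <- c(r, cc)
      k <- k + 1L
    }
  }
  colnames(out) <- c("row", "col")
  out
}

#' Build a snake-ordered mosaic around a center position
#'
#' Tiles lie on a grid with pitch `fov_um * (1 - overlap)`, centered on
#' `center`; the visit order is a snake starting at the top-left tile
#' (smallest x, smallest y) moving rightward. Ids are assigned "001",
#' "002", ... in visit order.
#'
#' @param center_x_um,center_y_um Mosaic center (µm).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param fov_um Square field of view per tile (µm).
#' @param overlap Overlap fraction between adjacent tiles, in `[0, 1)`.
#' @param travel_um Stage travel limit (µm).
#' @return A [roi_list()] in visit order.
#' @export
build_mosaic <- function(center_x_um, center_y_um, n_rows, n_cols, fov_um,
                         overlap = 0, travel_um = 10000) {
  if (n_rows < 1 || n_cols < 1) stop("mosaic needs n_rows, n_cols >= 1")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (fov_um <= 0) stop("fov must be > 0")
  pitch <- fov_um * (1 - overlap)
  xs <- center_x_um + (seq_len(n_cols) - (n_cols + 1) / 2) * pitch
  ys <- center_y_um + (seq_len(n_rows) - (n_rows + 1) / 2) * pitch
  ord <- snake_order(n_rows, n_cols)
  x <- xs[ord[, "col"]]
  y <- ys[ord[, "row"]]
  if (max(abs(x)) + fov_um / 2 > travel_um ||
      max(abs(y)) + fov_um / 2 > travel_um) {
    stop("mosaic grid exceeds stage travel of +/- ", travel_um, " um")
  }
  roi_list(x, y, travel_um = travel_um)
}

#' Interpolate tiles to cover a rectangular region
#'
#' Computes the minimal snake-ordered grid whose tile union covers the
#' axis-aligned rectangle spanned by two corners, with per-axis tile count
#' `max(1, ceil((span - fov) / pitch) + 1)` and pitch
#' `fov_um * (1 - overlap)`. Tiles start flush with the low edge of the
#' region.
#'
#' @param corner_a,corner_b Opposite region corners, numeric `c(x, y)` µm.
#' @param fov_um Square field of view per tile (µm).
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param travel_um Stage travel limit (µm).
#' @return A [roi_list()] in snake visit order.
#' @export
interpolate_region <- function(corner_a, corner_b, fov_um, overlap = 0,
                               travel_um = 10000) {
  stopifnot(length(corner_a) == 2, length(corner_b) == 2)
  if (all(corner_a == corner_b)) stop("region corners must be distinct")
  if (fov_um <= 0) stop("fov must be > 0")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  pitch <- fov_um * (1 - overlap)
  lo <- pmin(corner_a, corner_b)
  hi <- pmax(corner_a, corner_b)
  span <- hi - lo
  n_tiles <- pmax(1, ceiling((span - fov_um) / pitch) + 1)
  n_cols <- n_tiles[1]
  n_rows <- n_tiles[2]
  xs <- lo[1] + fov_um / 2 + (seq_len(n_cols) - 1) * pitch
  ys <- lo[2] + fov_um / 2 + (seq_len(n_rows) - 1) * pitch
  ord <- snake_order(n_rows, n_cols)
  x <- xs[ord[, "col"]]
  y <- ys[ord[, "row"]]
  if (max(abs(x)) + fov_um / 2 > travel_um ||
      max(abs(y)) + fov_um / 2 > travel_um) {
    stop("interpolated region exceeds stage travel of +/- ", travel_um, " um")
  }
  roi_list(x, y, travel_um = travel_um)
}

#' Save an ROI list as YAML
#'
#' Serialized as a sequence of mappings `{id, x_um, y_um, z_um?}`; the
#' `z_um` key is omitted where undefined.
#'
#' @param rois A [roi_list()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
roi_save <- function(rois, path) {
  entries <- lapply(seq_len(nrow(rois)), function(i) {
    e <- list(id = rois$id[i], x_um = rois$x_um[i], y_um = rois$y_um[i])
    if (!is.na(rois$z_um[i])) e$z_um <- rois$z_um[i]
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Load an ROI list from YAML
#'
#' Validates each entry (required keys, numeric coordinates, unique ids)
#' and reports the offending entry on failure.
#'
#' @param path YAML file written by [roi_save()] (or hand-authored).
#' @param travel_um Stage travel limit (µm).
#' @return A [roi_list()].
#' @export
roi_load <- function(path, travel_um = 10000) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  entries <- yaml::read_yaml(path)
  if (is.null(entries)) entries <- list()
  ids <- character(0); x <- y <- z <- numeric(0)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    for (k in c("id", "x_um", "y_um")) {
      if (is.null(e[[k]])) {
        stop(sprintf("ROI entry %d: missing field '%s'", i, k))
      }
    }
    if (!is.numeric(e$x_um) || !is.numeric(e$y_um)) {
      stop(sprintf("ROI entry %d ('%s'): coordinates must be numeric",
                   i, e$id))
    }
    if (as.character(e$id) %in% ids) {
      stop(sprintf("ROI file: duplicate id '%s' at entry %d", e$id, i))
    }
    ids <- c(ids, as.character(e$id))
    x <- c(x, e$x_um); y <- c(y, e$y_um)
    z <- c(z, if (is.null(e$z_um)) NA_real_ else e$z_um)
  }
  roi_list(x, y, z, ids = ids, travel_um = travel_um)
}
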