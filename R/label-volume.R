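#' Anisotropic 3D label volume
#'
#' The universe every operation in the package reads: a 3D grid of
#' non-negative integer labels (0 = background), the physical voxel spacing,
#' and a [label_table] naming every foreground label.
#'
#' Orientation contract: `y` is the apical-to-basal axis — apical surfaces
#' (microvilli, photoreceptor outer segments) face low `y`, Bruch's membrane
#' lies at high `y`; `x` is the lateral in-plane axis and `z` the slice
#' (sectioning) axis. Internally the grid is stored as an R array with
#' `dim = c(ny, nx, nz)` so that slice `k` is the contiguous matrix
#' `grid[, , k]` (rows = y, columns = x); this is the column-major
#' equivalent of the `(z, y, x)` slice-major convention used by array
#' libraries elsewhere.
#'
#' @param grid 3D integer array, `dim = c(ny, nx, nz)`, values >= 0.
#' @param spacing A [voxel_spacing] (nm).
#' @param table A [label_table] covering every foreground label in `grid`.
#'
#' @return An object of class `label_volume`: list with elements `grid`,
#'   `spacing`, `table`.
#' @export
label_volume <- function(grid, spacing, table) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop("grid must be a 3D array", call. = FALSE)
  }
  if (is.double(grid)) {
    if (any(grid != floor(grid), na.rm = TRUE)) {
      stop("grid contains non-integer pixel data", call. = FALSE)
    }
    storage.mode(grid) <- "integer"
  }
  if (!is.integer(grid)) stop("grid must be integer-valued", call. = FALSE)
  if (anyNA(grid) || any(grid < 0L)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  if (!is_voxel_spacing(spacing)) {
    stop("spacing must be a voxel_spacing object", call. = FALSE)
  }
  if (!inherits(table, "label_table")) {
    stop("table must be a label_table", call. = FALSE)
  }
  present <- sort(unique(as.vector(grid)))
  present <- present[present > 0L]
  missing <- setdiff(present, table$label)
  if (length(missing) > 0) {
    stop("unknown label id(s) in volume, absent from label table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(grid = grid, spacing = spacing, table = table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<label_volume> %d x %d x %d voxels (y, x, z) at %g x %g x %g nm\n",
    d[1], d[2], d[3], x$spacing$dy, x$spacing$dx, x$spacing$dz))
  cat(sprintf("  %d labels over %d cells\n", nrow(x$table),
              length(unique(x$table$cell))))
  invisible(x)
}

#' Cell identifiers present in a volume
#'
#' @param vol A [label_volume].
#' @param kind Restrict to cells owning at least one label of this
#'   compartment kind (default: cells with a `cell_body`).
#' @return Character vector of cell ids.
#' @export
cell_ids <- function(vol, kind = "cell_body") {
  sort(unique(vol$table$cell[vol$table$compartment %in% kind]))
}

#' Binary mask of one (cell, compartment) pair
#'
#' True exactly where the voxel's label maps to the requested cell and
#' compartment; the union over all matching labels (a bi-nucleate cell's
#' nucleus mask covers both nuclei). A pair with no matching label yields an
#' empty mask with a warning, not an error — a cell may genuinely lack basal
#' infolds.
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @param kind One of [compartment_kinds].
#' @return Logical array of the grid's dimensions.
#' @export
compartment_mask <- function(vol, cell_id, kind) {
  kind <- match.arg(kind, compartment_kinds)
  labs <- labels_for(vol$table, cell = cell_id, compartment = kind)
  if (length(labs) == 0L) {
    warning(sprintf("no '%s' label for cell '%s'; returning empty mask",
                    kind, cell_id), call. = FALSE)
    return(array(FALSE, dim(vol$grid)))
  }
  mask_of_labels(vol$grid, labs)
}

# union mask over a set of label ids (fast path for a single id)
mask_of_labels <- function(grid, labels) {
  if (length(labels) == 1L) {
    m <- grid == labels
  } else {
    m <- array(match(grid, labels, nomatch = 0L) > 0L, dim(grid))
  }
  m
}

#' Read a multi-page TIFF label stack
#'
#' Pages must be identically shaped unsigned-integer images; page order is
#' slice (z) order. Every foreground label must be present in the label
#' table — an unknown label is an error, because silent unlabelled objects
#' would corrupt every downstream measurement.
#'
#' @param path Multi-page TIFF file.
#' @param spacing A [voxel_spacing]; if `NULL`, taken from the label table
#'   JSON's `spacing_nm` field (an error if absent there too).
#' @param table_path Path to the JSON label table
#'   (see [read_label_table]).
#' @return A [label_volume].
#' @export
read_label_stack <- function(path, spacing = NULL, table_path) {
  if (!file.exists(path)) stop("stack not found: ", path, call. = FALSE)
  tab <- read_label_table(table_path)
  if (is.null(spacing)) {
    spacing <- attr(tab, "spacing")
    if (is.null(spacing)) {
      stop("spacing not supplied and label table JSON has no spacing_nm",
           call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("inconsistent page shapes in ", path, call. = FALSE)
  }
  if (length(dims[[1]]) != 2L) {
    stop("expected single-channel (grey) integer pages", call. = FALSE)
  }
  grid <- array(0L, c(dims[[1]][1], dims[[1]][2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (is.double(pg) && any(pg != floor(pg))) {
      stop("non-integer pixel data in page ", k, call. = FALSE)
    }
    grid[, , k] <- as.integer(pg)
  }
  label_volume(grid, spacing, tab)
}

#' Write a label volume as a multi-page TIFF
#'
#' Lossless unsigned-integer round trip: 8-bit when the maximum label fits,
#' 16-bit up to 65535 (labels above 65535 are refused — the on-disk format
#' is capped at 16-bit unsigned).
#'
#' @param vol A [label_volume].
#' @param path Output TIFF path.
#' @param table_path Optional path for the companion JSON label table
#'   (written with the volume's spacing when given).
#' @return `path`, invisibly.
#' @export
write_label_stack <- function(vol, path, table_path = NULL) {
  maxlab <- max(vol$grid, 0L)
  if (maxlab > 65535L) {
    stop("labels above 65535 cannot be stored in 16-bit TIFF", call. = FALSE)
  }
  bits <- if (maxlab <= 255L) 8L else 16L
  scale <- 2^bits - 1
  nz <- dim(vol$grid)[3]
  pages <- lapply(seq_len(nz), function(k) vol$grid[, , k] / scale)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits,
                    compression = "none"),
    error = function(e) stop("cannot write TIFF at ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(table_path)) {
    write_label_table(vol$table, table_path, spacing = vol$spacing)
  }
  invisible(path)
}

# --- internal geometry helpers -------------------------------------------

# bounding box of TRUE voxels; NULL if empty.
mask_bbox <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  d <- dim(mask)
  iy <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  jx <- rest %% d[2] + 1L
  kz <- rest %/% d[2] + 1L
  list(y = range(iy), x = range(jx), z = range(kz))
}

# pad + clamp a bbox
pad_bbox <- function(bb, d, pad = 1L, pad_z = pad) {
  list(y = c(max(1L, bb$y[1] - pad), min(d[1], bb$y[2] + pad)),
       x = c(max(1L, bb$x[1] - pad), min(d[2], bb$x[2] + pad)),
       z = c(max(1L, bb$z[1] - pad_z), min(d[3], bb$z[2] + pad_z)))
}

merge_bbox <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  list(y = range(c(a$y, b$y)), x = range(c(a$x, b$x)), z = range(c(a$z, b$z)))
}

crop_bbox <- function(arr, bb) {
  arr[bb$y[1]:bb$y[2], bb$x[1]:bb$x[2], bb$z[1]:bb$z[2], drop = FALSE]
}

# one-pass per-label bounding boxes + voxel counts (data.table)
label_bboxes <- function(grid, labels = NULL) {
  idx <- which(grid != 0L)
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), n_vox = integer(),
                          y0 = integer(), y1 = integer(), x0 = integer(),
                          x1 = integer(), z0 = integer(), z1 = integer()))
  }
  d <- dim(grid)
  lab <- grid[idx]
  if (!is.null(labels)) {
    keep <- lab %in% labels
    idx <- idx[keep]; lab <- lab[keep]
  }
  iy <- (idx - 1L) %% d[1] + 1L
  rest <- (idx - 1L) %/% d[1]
  jx <- rest %% d[2] + 1L
  kz <- rest %/% d[2] + 1L
  dt <- data.table::data.table(label = lab, iy = iy, jx = jx, kz = kz)
  agg <- dt[, list(n_vox = .N, y0 = min(iy), y1 = max(iy), x0 = min(jx),
                   x1 = max(jx), z0 = min(kz), z1 = max(kz)),
            by = "label"]
  data.table::setorder(agg, label)
  tibble::as_tibble(agg)
}

# bbox (list form) of a set of labels from a label_bboxes tibble
bbox_of_labels <- function(bbs, labels) {
  rows <- bbs[bbs$label %in% labels, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  list(y = c(min(rows$y0), max(rows$y1)),
       x = c(min(rows$x0), max(rows$x1)),
       z = c(min(rows$z0), max(rows$z1)))
}
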