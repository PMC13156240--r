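#' Gridded raster data model
#'
#' A `rh_grid` is a lightweight single-band raster: a numeric matrix with a
#' square cell size and a top-left world origin, north-up and row-major.
#' Missing cells are stored as `NA` internally; a `nodata` sentinel is used
#' only when the grid is written to or read from disk.  World coordinates
#' refer to cell centers; all distances are in meters and areas in km^2.
#'
#' @param values numeric (or integer, for categorical grids) matrix.
#' @param cell_size cell edge length in meters (> 0).
#' @param origin_x,origin_y world coordinates (m) of the grid's top-left
#'   corner (not the first cell center).
#' @param kind `"continuous"` or `"categorical"`.  Categorical grids must
#'   hold integer codes and are resampled by nearest neighbor.
#' @return an object of class `rh_grid`.
#' @export
grid_create <- function(values, cell_size, origin_x = 0, origin_y = NULL,
                        kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (is.null(origin_y)) origin_y <- nrow(values) * cell_size
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical grids must hold integer codes")
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         kind = kind),
    class = "rh_grid")
}

#' @export
print.rh_grid <- function(x, ...) {
  cat(sprintf("<rh_grid %s> %d x %d cells @ %g m, origin (%g, %g), %d NA\n",
              x$kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_x, x$origin_y, sum(is.na(x$values))))
  invisible(x)
}

is_grid <- function(x) inherits(x, "rh_grid")

#' @rdname grid_create
#' @param x object to test.
#' @export
is_mask <- function(x) {
  is_grid(x) && is.logical(x$is_mask_flag %||% FALSE) && isTRUE(x$is_mask_flag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      a$cell_size != b$cell_size ||
      abs(a$origin_x - b$origin_x) > 1e-6 || abs(a$origin_y - b$origin_y) > 1e-6)
    stop("grids do not share geometry")
  invisible(TRUE)
}

#' Logical membership mask sharing a parent grid's geometry
#'
#' @param member logical matrix (TRUE = member; NA treated as FALSE).
#' @param template an `rh_grid` supplying geometry, or NULL with
#'   `cell_size`/`origin_*` given explicitly.
#' @inheritParams grid_create
#' @return an `rh_mask` (also an `rh_grid` holding 0/1).
#' @export
mask_create <- function(member, template = NULL, cell_size = NULL,
                        origin_x = 0, origin_y = NULL) {
  if (!is.matrix(member)) member <- as.matrix(member)
  member[is.na(member)] <- FALSE
  m <- member
  storage.mode(m) <- "logical"
  if (!is.null(template)) {
    cell_size <- template$cell_size
    origin_x <- template$origin_x
    origin_y <- template$origin_y
    if (!identical(dim(m), dim(template$values)))
      stop("mask does not match template geometry")
  }
  g <- grid_create(m * 1, cell_size, origin_x, origin_y, kind = "categorical")
  g$member <- m
  class(g) <- c("rh_mask", "rh_grid")
  g
}

#' @export
print.rh_mask <- function(x, ...) {
  cat(sprintf("<rh_mask> %d x %d cells @ %g m, %d members (%.4g km^2)\n",
              nrow(x$member), ncol(x$member), x$cell_size,
              sum(x$member), area_km2(x)))
  invisible(x)
}

# world coordinates of all cell centers, row-major
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  list(x = grid$origin_x + (seq_len(nc) - 0.5) * cs,
       y = grid$origin_y - (seq_len(nr) - 0.5) * cs)
}

# (row, col) of the cell containing world point (x, y); NA outside
cell_at <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin_x) / cs) + 1
  row <- floor((grid$origin_y - y) / cs) + 1
  bad <- col < 1 | col > ncol(grid$values) | row < 1 | row > nrow(grid$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# world center of (row, col)
cell_center_xy <- function(grid, row, col) {
  cs <- grid$cell_size
  cbind(x = grid$origin_x + (col - 0.5) * cs,
        y = grid$origin_y - (row - 0.5) * cs)
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# offsets (dr, dc) of cells whose centers lie within `radius` of the focal
# cell center (inclusive), excluding or including the center itself
kernel_offsets <- function(radius, cell_size, include_center = TRUE) {
  r <- floor(radius / cell_size + 1e-9)
  dr <- rep(-r:r, each = 2 * r + 1)
  dc <- rep(-r:r, times = 2 * r + 1)
  keep <- sqrt(dr^2 + dc^2) * cell_size <= radius + 1e-9
  if (!include_center) keep <- keep & !(dr == 0 & dc == 0)
  cbind(dr = dr[keep], dc = dc[keep])
}

#' Resample a grid to a new cell size
#'
#' Continuous grids are resampled by bilinear interpolation of cell-center
#' values; categorical grids use nearest neighbor (interpolating class codes
#' is meaningless).  The output covers the input extent with the same origin.
#'
#' @param grid an `rh_grid`.
#' @param target_cell target cell size in meters (> 0).
#' @return an `rh_grid` at the new resolution.
#' @export
resample <- function(grid, target_cell) {
  stopifnot(is_grid(grid))
  if (!is.numeric(target_cell) || target_cell <= 0)
    stop("target_cell must be > 0")
  cs <- grid$cell_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  width <- nc * cs; height <- nr * cs
  nc2 <- max(1L, ceiling(width / target_cell - 1e-9))
  nr2 <- max(1L, ceiling(height / target_cell - 1e-9))
  # target cell centers in source fractional index space (1-based)
  xs <- ((seq_len(nc2) - 0.5) * target_cell) / cs + 0.5
  ys <- ((seq_len(nr2) - 0.5) * target_cell) / cs + 0.5
  v <- grid$values
  if (grid$kind == "categorical") {
    ri <- pmin(pmax(round(ys), 1), nr)
    ci <- pmin(pmax(round(xs), 1), nc)
    out <- v[ri, ci, drop = FALSE]
  } else {
    r0 <- pmin(pmax(floor(ys), 1), nr); r1 <- pmin(r0 + 1, nr)
    c0 <- pmin(pmax(floor(xs), 1), nc); c1 <- pmin(c0 + 1, nc)
    fy <- pmin(pmax(ys - r0, 0), 1); fx <- pmin(pmax(xs - c0, 0), 1)
    FY <- matrix(fy, nr2, nc2); FX <- matrix(fx, nr2, nc2, byrow = TRUE)
    v00 <- v[r0, c0, drop = FALSE]; v01 <- v[r0, c1, drop = FALSE]
    v10 <- v[r1, c0, drop = FALSE]; v11 <- v[r1, c1, drop = FALSE]
    out <- v00 * (1 - FY) * (1 - FX) + v01 * (1 - FY) * FX +
      v10 * FY * (1 - FX) + v11 * FY * FX
    # fall back to nearest neighbor where any corner is NA
    if (anyNA(out)) {
      ri <- pmin(pmax(round(ys), 1), nr); ci <- pmin(pmax(round(xs), 1), nc)
      nn <- v[ri, ci, drop = FALSE]
      out[is.na(out)] <- nn[is.na(out)]
    }
  }
  grid_create(out, target_cell, grid$origin_x, grid$origin_y, kind = grid$kind)
}

#' Focal (moving-window) statistic over a circular neighborhood
#'
#' Per cell, the statistic of all cells whose centers lie within `radius`
#' of the focal cell center (center cell included).  `NA` cells are excluded;
#' at grid edges the neighborhood shrinks to the available cells.  A cell
#' whose whole neighborhood is `NA` stays `NA`.
#'
#' @param grid an `rh_grid`.
#' @param radius neighborhood radius in meters (>= cell size).
#' @param stat `"mean"` (others may be added as needed).
#' @return an `rh_grid` of the same geometry.
#' @export
focal_stat <- function(grid, radius, stat = c("mean", "sum", "count")) {
  stat <- match.arg(stat)
  stopifnot(is_grid(grid))
  if (radius < grid$cell_size)
    stop("radius must be at least one cell size")
  off <- kernel_offsets(radius, grid$cell_size)
  v <- grid$values
  ok <- !is.na(v)
  v0 <- v; v0[!ok] <- 0
  s <- matrix(0, nrow(v), ncol(v)); n <- matrix(0, nrow(v), ncol(v))
  for (i in seq_len(nrow(off))) {
    s <- s + shift_mat(v0, off[i, 1], off[i, 2], fill = 0)
    n <- n + shift_mat(ok * 1, off[i, 1], off[i, 2], fill = 0)
  }
  out <- switch(stat,
                mean = ifelse(n > 0, s / n, NA_real_),
                sum = ifelse(n > 0, s, NA_real_),
                count = n)
  grid_create(out, grid$cell_size, grid$origin_x, grid$origin_y,
              kind = "continuous")
}

# exact 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher);
# positions with f = Inf contribute no parabola
dt1d <- function(f) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (length(idx) == 0L) return(rep(Inf, n))
  # squared indices can exceed .Machine$integer.max on long rows
  storage.mode(idx) <- "double"
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- idx[1]; z[1] <- -Inf; z[2] <- Inf
  for (q in idx[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

# exact squared EDT (in cells) of a logical matrix; Inf where no member
edt_sq <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  f <- matrix(Inf, nr, nc)
  f[member] <- 0
  # columns
  for (j in seq_len(nc)) {
    col <- f[, j]
    if (all(!is.finite(col))) next
    f[, j] <- dt1d(col)
  }
  # rows
  for (i in seq_len(nr)) {
    row <- f[i, ]
    if (all(!is.finite(row))) next
    f[i, ] <- dt1d(row)
  }
  f
}

#' Euclidean distance to the nearest mask member
#'
#' Exact cell-center-to-cell-center Euclidean distance (meters) from every
#' cell to the nearest member cell of `mask`; member cells get 0.
#'
#' @param mask an `rh_mask` with at least one member.
#' @return a continuous `rh_grid` of distances in meters.
#' @export
distance_to <- function(mask) {
  stopifnot(inherits(mask, "rh_mask"))
  if (!any(mask$member)) stop("distance_to: mask is empty")
  d <- sqrt(edt_sq(mask$member)) * mask$cell_size
  grid_create(d, mask$cell_size, mask$origin_x, mask$origin_y,
              kind = "continuous")
}

#' Buffer a mask outward by a radius
#'
#' Cell-center rule: the buffer contains every cell whose center lies within
#' `radius` of some member cell center.  `radius = 0` returns the input.
#'
#' @param mask an `rh_mask`.
#' @param radius buffer distance in meters (>= 0).
#' @return an `rh_mask`.
#' @export
buffer_mask <- function(mask, radius) {
  stopifnot(inherits(mask, "rh_mask"))
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0 || !any(mask$member)) return(mask)
  d <- sqrt(edt_sq(mask$member)) * mask$cell_size
  mask_create(d <= radius + 1e-9, template = mask)
}

#' Area of a mask in square kilometers
#'
#' @param mask an `rh_mask`.
#' @return member-cell count times cell_size^2 / 1e6.
#' @export
area_km2 <- function(mask) {
  stopifnot(inherits(mask, "rh_mask"))
  sum(mask$member) * mask$cell_size^2 / 1e6
}

#' Set algebra on masks
#'
#' @param a,b `rh_mask` objects on the same geometry.
#' @return an `rh_mask`.
#' @export
mask_union <- function(a, b) {
  stopifnot_same_geometry(a, b)
  mask_create(a$member | b$member, template = a)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  stopifnot_same_geometry(a, b)
  mask_create(a$member & b$member, template = a)
}

#' @rdname mask_union
#' @export
mask_diff <- function(a, b) {
  stopifnot_same_geometry(a, b)
  mask_create(a$member & !b$member, template = a)
}

#' Mask from a predicate on grid values
#'
#' @param grid an `rh_grid`.
#' @param predicate function mapping the value matrix to a logical matrix,
#'   or a set of codes to match for categorical grids.
#' @return an `rh_mask` (NA grid cells are non-members).
#' @export
grid_mask <- function(grid, predicate) {
  stopifnot(is_grid(grid))
  m <- if (is.function(predicate)) predicate(grid$values)
  else !is.na(grid$values) & (grid$values %in% predicate)
  m[is.na(m)] <- FALSE
  mask_create(m, template = grid)
}

#' Read / write grids as ESRI ASCII rasters
#'
#' Plain-text single-band raster exchange (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows top to bottom).  Masks are
#' written as 0/1 integers.
#'
#' @param grid an `rh_grid` or `rh_mask`.
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written for continuous grids.
#' @export
grid_write_asc <- function(grid, path, digits = 7) {
  stopifnot(is_grid(grid))
  v <- if (inherits(grid, "rh_mask")) grid$member * 1 else grid$values
  nodata <- -9999
  v[is.na(v)] <- nodata
  nr <- nrow(v)
  con <- file(path, "w")
  on.exit(close(con))
  yll <- grid$origin_y - nr * grid$cell_size
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.6f", grid$origin_x),
    sprintf("yllcorner %.6f", yll),
    sprintf("cellsize %.6f", grid$cell_size),
    sprintf("NODATA_value %d", nodata)), con)
  fmt <- if (grid$kind == "categorical" || inherits(grid, "rh_mask")) "%d"
  else paste0("%.", digits, "g")
  for (i in seq_len(nr)) {
    row <- v[i, ]
    if (fmt == "%d") row <- as.integer(round(row))
    writeLines(paste(sprintf(fmt, row), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname grid_write_asc
#' @param kind `"continuous"`, `"categorical"`, or `"mask"`.
#' @export
grid_read_asc <- function(path, kind = "continuous") {
  hdr <- list()
  lines <- readLines(path)
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  v <- do.call(rbind, vals)
  stopifnot(nrow(v) == hdr$nrows, ncol(v) == hdr$ncols)
  v[v == hdr$nodata_value] <- NA
  origin_y <- hdr$yllcorner + hdr$nrows * hdr$cellsize
  if (kind == "mask")
    mask_create(!is.na(v) & v != 0, cell_size = hdr$cellsize,
                origin_x = hdr$xllcorner, origin_y = origin_y)
  else grid_create(v, hdr$cellsize, hdr$xllcorner, origin_y, kind = kind)
}
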