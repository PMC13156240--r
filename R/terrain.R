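# Terrain and hydrology derivations: slope, topographic position, geomorphon
# landforms, depression-filled D8 routing, Strahler-ordered headwater
# flowlines, and the five-rule flowline cleaning cascade.

# neighbor offsets, clockwise from north; diagonals have distance factor sqrt(2)
D8_OFFSETS <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                    dc = c(0, 1, 1, 1, 0, -1, -1, -1))
D8_DIST <- sqrt(D8_OFFSETS[, 1]^2 + D8_OFFSETS[, 2]^2)

#' Mean slope within a circular neighborhood
#'
#' Per-cell slope in degrees from Horn's 3x3 finite differences (edges use
#' replicated border values), followed by a circular focal mean.
#'
#' @param dem an elevation `rh_grid` (meters).
#' @param radius focal-mean radius in meters; `NULL` skips the smoothing.
#' @return a continuous `rh_grid` of slopes in degrees.
#' @export
slope <- function(dem, radius = 120) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  # pad by edge replication so Horn's kernel is defined everywhere
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  at <- function(dr, dc) zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- ((at(-1, 1) + 2 * at(0, 1) + at(1, 1)) -
           (at(-1, -1) + 2 * at(0, -1) + at(1, -1))) / (8 * cs)
  gy <- ((at(1, -1) + 2 * at(1, 0) + at(1, 1)) -
           (at(-1, -1) + 2 * at(-1, 0) + at(-1, 1))) / (8 * cs)
  deg <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  g <- grid_create(deg, cs, dem$origin_x, dem$origin_y)
  if (is.null(radius)) g else focal_stat(g, radius, "mean")
}

#' Topographic position index
#'
#' Elevation minus the circular focal-mean elevation: positive on ridges,
#' negative in valleys, zero on constants (shift-invariant).
#'
#' @inheritParams slope
#' @return a continuous `rh_grid`.
#' @export
tpi <- function(dem, radius = 120) {
  m <- focal_stat(dem, radius, "mean")
  grid_create(dem$values - m$values, dem$cell_size, dem$origin_x,
              dem$origin_y)
}

# geomorphon lookup by (number of '-', number of '+') symbols; codes:
# 1 Flat, 2 Peak, 3 Ridge, 4 Shoulder, 5 Spur, 6 Slope, 7 Hollow,
# 8 Footslope, 9 Valley, 10 Pit
geomorphon_table <- function() {
  L <- matrix(NA_integer_, 9, 9)
  set <- function(minus, plus, code) L[minus + 1, plus + 1] <<- code
  rows <- list(
    c(1, 1, 1, 8, 8, 9, 9, 9, 10),  # minus = 0
    c(1, 1, 8, 8, 8, 9, 9, 9),      # 1
    c(1, 4, 6, 6, 7, 7, 9),         # 2
    c(4, 4, 6, 6, 6, 7),            # 3
    c(4, 4, 5, 6, 6),               # 4
    c(3, 3, 5, 5),                  # 5
    c(3, 3, 5),                     # 6
    c(3, 3),                        # 7
    c(2))                           # 8
  for (m in 0:8) for (p in seq_along(rows[[m + 1]]) - 1)
    set(m, p, rows[[m + 1]][p + 1])
  L
}

#' Geomorphon landform classification
#'
#' For each cell and each of the 8 compass directions, the largest upward and
#' downward line-of-sight angles to cells between `skip_cells` (exclusive)
#' and `search_cells` (inclusive) are compared against a flatness threshold
#' to produce a ternary symbol; the counts of `+` (terrain above) and `-`
#' (terrain below) symbols index the standard 10-class lookup table.
#' Windows that run off the grid shrink to the available cells.
#'
#' @param dem an elevation `rh_grid`.
#' @param search_cells lookout distance in cells.
#' @param skip_cells cells skipped next to the focal cell (smoothing).
#' @param flat_deg flatness threshold in degrees.
#' @return a categorical `rh_grid` with codes 1-10.
#' @export
geomorphons <- function(dem, search_cells = 10, skip_cells = 3,
                        flat_deg = 1.0) {
  stopifnot(is_grid(dem), search_cells > skip_cells, skip_cells >= 0)
  z <- dem$values
  cs <- dem$cell_size
  nr <- nrow(z); nc <- ncol(z)
  nplus <- matrix(0L, nr, nc); nminus <- matrix(0L, nr, nc)
  for (d in seq_len(8)) {
    dr <- D8_OFFSETS[d, 1]; dc <- D8_OFFSETS[d, 2]
    up <- matrix(-Inf, nr, nc); down <- matrix(Inf, nr, nc)
    for (k in (skip_cells + 1):search_cells) {
      zs <- shift_mat(z, -k * dr, -k * dc)     # value of cell k steps away
      ang <- atan2(zs - z, k * D8_DIST[d] * cs) * 180 / pi
      up <- pmax(up, ang, na.rm = TRUE)
      down <- pmin(down, ang, na.rm = TRUE)
    }
    upa <- ifelse(is.finite(up), up, 0)
    dna <- ifelse(is.finite(down), -down, 0)   # magnitude of downward angle
    plus <- (upa > flat_deg | dna > flat_deg) & (upa > dna)
    minus <- (upa > flat_deg | dna > flat_deg) & (dna > upa)
    nplus <- nplus + plus
    nminus <- nminus + minus
  }
  L <- geomorphon_table()
  code <- matrix(L[cbind(as.vector(nminus) + 1L, as.vector(nplus) + 1L)],
                 nr, nc)
  code[is.na(z)] <- NA_integer_
  grid_create(code, cs, dem$origin_x, dem$origin_y, kind = "categorical")
}

#' Fill closed depressions (Planchon-Darboux with epsilon gradient)
#'
#' Iteratively lowers an initially flooded surface toward the DEM while
#' keeping a strictly positive drainage gradient of `eps` per step, so every
#' interior cell drains to the grid border.
#'
#' @param dem an elevation `rh_grid`.
#' @param eps minimum elevation drop per cell step (meters).
#' @param max_iter iteration cap.
#' @return the filled elevation `rh_grid`.
#' @export
fill_depressions <- function(dem, eps = 1e-4, max_iter = 5000) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  W <- matrix(Inf, nr, nc)
  border <- matrix(FALSE, nr, nc)
  border[1, ] <- TRUE; border[nr, ] <- TRUE
  border[, 1] <- TRUE; border[, nc] <- TRUE
  border[is.na(z)] <- FALSE
  # NA cells act as drains: anything next to NA is effectively on the border
  if (anyNA(z)) {
    nb_na <- matrix(FALSE, nr, nc)
    for (d in seq_len(8))
      nb_na <- nb_na | shift_mat(is.na(z), D8_OFFSETS[d, 1], D8_OFFSETS[d, 2],
                                 fill = FALSE)
    border <- border | (nb_na & !is.na(z))
  }
  W[border] <- z[border]
  for (it in seq_len(max_iter)) {
    m <- matrix(Inf, nr, nc)
    for (d in seq_len(8)) {
      Ws <- shift_mat(W, D8_OFFSETS[d, 1], D8_OFFSETS[d, 2], fill = Inf)
      m <- pmin(m, Ws + eps * D8_DIST[d])
    }
    Wn <- pmax(z, pmin(W, m))
    Wn[is.na(z)] <- NA
    Wn[border] <- z[border]
    done <- isTRUE(all.equal(Wn[!is.na(z)], W[!is.na(z)], tolerance = 0))
    W <- Wn
    if (done) break
  }
  grid_create(W, dem$cell_size, dem$origin_x, dem$origin_y)
}

#' D8 flow direction and accumulation
#'
#' Depressions are filled first, then every cell drains to its
#' steepest-descent 8-neighbor.  Accumulation counts the number of upstream
#' cells draining through each cell (the cell itself excluded).  Direction
#' codes are 1-8 clockwise from north; 0 marks cells draining off-grid.
#'
#' @param dem an elevation `rh_grid`.
#' @param eps epsilon gradient used for depression filling.
#' @return list with `direction` (categorical `rh_grid`), `accumulation`
#'   (continuous `rh_grid`), and `filled` (the filled DEM).
#' @export
d8_flow <- function(dem, eps = 1e-4) {
  filled <- fill_depressions(dem, eps = eps)
  W <- filled$values
  nr <- nrow(W); nc <- ncol(W)
  best <- matrix(0, nr, nc)     # best descent gradient
  dir <- matrix(0L, nr, nc)
  for (d in seq_len(8)) {
    Ws <- shift_mat(W, -D8_OFFSETS[d, 1], -D8_OFFSETS[d, 2], fill = Inf)
    g <- (W - Ws) / D8_DIST[d]
    g[is.na(g)] <- -Inf
    upd <- g > best
    best[upd] <- g[upd]
    dir[upd] <- d
  }
  dir[is.na(W)] <- NA_integer_
  # accumulate from high to low; strictly decreasing along flow by eps
  ord <- order(W, decreasing = TRUE, na.last = NA)
  acc <- matrix(0, nr, nc)
  rows <- ((ord - 1L) %% nr) + 1L
  cols <- ((ord - 1L) %/% nr) + 1L
  for (k in seq_along(ord)) {
    r <- rows[k]; cc <- cols[k]
    dd <- dir[r, cc]
    if (is.na(dd) || dd == 0L) next
    tr <- r + D8_OFFSETS[dd, 1]; tc <- cc + D8_OFFSETS[dd, 2]
    if (tr < 1 || tr > nr || tc < 1 || tc > nc || is.na(W[tr, tc])) next
    acc[tr, tc] <- acc[tr, tc] + acc[r, cc] + 1
  }
  acc[is.na(W)] <- NA
  list(direction = grid_create(dir, dem$cell_size, dem$origin_x,
                               dem$origin_y, kind = "categorical"),
       accumulation = grid_create(acc, dem$cell_size, dem$origin_x,
                                  dem$origin_y),
       filled = filled)
}

# Strahler orders from downstream links (down[s] = index of the segment s
# flows into, NA at outlets): order 1 at sources; at a junction, two or more
# tributaries of maximal order k yield k + 1, otherwise the maximum carries.
strahler_from_links <- function(down) {
  n <- length(down)
  ord <- rep(NA_integer_, n)
  inc <- lapply(seq_len(n), function(s) which(down == s))
  pending <- seq_len(n)
  while (length(pending)) {
    progressed <- FALSE
    for (s in pending) {
      ups <- inc[[s]]
      if (length(ups) == 0) { ord[s] <- 1L; progressed <- TRUE }
      else if (all(!is.na(ord[ups]))) {
        m <- max(ord[ups])
        ord[s] <- if (sum(ord[ups] == m) >= 2) m + 1L else m
        progressed <- TRUE
      }
    }
    pending <- which(is.na(ord))
    if (!progressed && length(pending))
      stop("cycle detected in flow network")  # nocov
  }
  ord
}

seg_geometry <- function(cells, cs) {
  n <- nrow(cells)
  if (n < 2) return(list(length = 0, sinuosity = 1))
  steps <- sqrt(diff(cells[, 1])^2 + diff(cells[, 2])^2) * cs
  len <- sum(steps)
  chord <- sqrt((cells[n, 1] - cells[1, 1])^2 +
                  (cells[n, 2] - cells[1, 2])^2) * cs
  sin <- if (chord == 0) Inf else len / chord
  list(length = len, sinuosity = max(1, sin))
}

#' Extract a Strahler-ordered headwater flowline network
#'
#' Stream cells are those with flow accumulation at or above `threshold`.
#' They are linked along D8 directions, split into segments at junctions,
#' assigned Strahler orders (two order-k tributaries make k+1, otherwise the
#' maximum carries through), and only orders in `keep_orders` are retained.
#'
#' @param accumulation accumulation `rh_grid` from [d8_flow()].
#' @param direction direction `rh_grid` from [d8_flow()].
#' @param threshold accumulation threshold in cells (default 300).
#' @param keep_orders Strahler orders to retain (default 1:2, headwaters).
#' @param max_reach_len segments longer than this are subdivided into
#'   equal reach-length pieces (m); `Inf` disables.
#' @return an `rh_flownet`: list of segments, each with `cells` (row/col
#'   matrix ordered downstream), `length_m`, `sinuosity`, `strahler`,
#'   `downstream` (segment index or NA).
#' @export
extract_flowlines <- function(accumulation, direction, threshold = 300,
                              keep_orders = 1:2, max_reach_len = 1000) {
  stopifnot(threshold >= 1)
  acc <- accumulation$values; dir <- direction$values
  nr <- nrow(acc); nc <- ncol(acc); cs <- accumulation$cell_size
  stream <- !is.na(acc) & acc >= threshold
  net <- structure(list(segments = list(), cell_size = cs,
                        origin_x = accumulation$origin_x,
                        origin_y = accumulation$origin_y,
                        dim = c(nr, nc)),
                   class = "rh_flownet")
  if (!any(stream)) return(net)
  idx <- function(r, c) (c - 1L) * nr + r
  target_of <- function(r, c) {
    dd <- dir[r, c]
    if (is.na(dd) || dd == 0L) return(NULL)
    tr <- r + D8_OFFSETS[dd, 1]; tc <- c + D8_OFFSETS[dd, 2]
    if (tr < 1 || tr > nr || tc < 1 || tc > nc || !stream[tr, tc]) return(NULL)
    c(tr, tc)
  }
  scells <- which(stream, arr.ind = TRUE)
  indeg <- integer(nr * nc)
  for (i in seq_len(nrow(scells))) {
    t <- target_of(scells[i, 1], scells[i, 2])
    if (!is.null(t)) indeg[idx(t[1], t[2])] <- indeg[idx(t[1], t[2])] + 1L
  }
  is_start <- indeg[idx(scells[, 1], scells[, 2])] != 1L
  starts <- scells[is_start, , drop = FALSE]
  segments <- list()
  start_seg_of <- integer(nr * nc)  # segment starting at a given cell
  for (i in seq_len(nrow(starts))) {
    r <- starts[i, 1]; cc <- starts[i, 2]
    cells <- matrix(c(r, cc), 1, 2)
    repeat {
      t <- target_of(cells[nrow(cells), 1], cells[nrow(cells), 2])
      if (is.null(t)) break
      if (indeg[idx(t[1], t[2])] >= 2L) { attr(cells, "junction") <- t; break }
      cells <- rbind(cells, t)
    }
    segments[[length(segments) + 1L]] <- cells
    start_seg_of[idx(r, cc)] <- length(segments)
  }
  # downstream segment = the one starting at the junction cell we flow into
  down <- rep(NA_integer_, length(segments))
  for (s in seq_along(segments)) {
    j <- attr(segments[[s]], "junction")
    if (!is.null(j)) down[s] <- start_seg_of[idx(j[1], j[2])]
  }
  ord <- strahler_from_links(down)
  # subdivide long segments into reach-length pieces (the thinning unit in
  # occurrence processing is one reach, as in real hydrography layers)
  pieces <- list(); piece_down <- integer(0); piece_ord <- integer(0)
  first_piece <- last_piece <- integer(length(segments))
  for (s in seq_along(segments)) {
    cells <- segments[[s]]
    attr(cells, "junction") <- NULL
    geo <- seg_geometry(cells, cs)
    n_piece <- if (is.finite(max_reach_len) && geo$length > max_reach_len)
      ceiling(geo$length / max_reach_len) else 1L
    cuts <- round(seq(0, nrow(cells), length.out = n_piece + 1))
    first_piece[s] <- length(pieces) + 1L
    for (q in seq_len(n_piece)) {
      sub <- cells[(cuts[q] + 1):cuts[q + 1], , drop = FALSE]
      pieces[[length(pieces) + 1L]] <- sub
      piece_ord <- c(piece_ord, ord[s])
      piece_down <- c(piece_down,
                      if (q < n_piece) length(pieces) + 1L else NA_integer_)
    }
    last_piece[s] <- length(pieces)
  }
  for (s in seq_along(segments)) {
    if (!is.na(down[s])) piece_down[last_piece[s]] <- first_piece[down[s]]
  }
  keep <- which(piece_ord %in% keep_orders)
  remap <- match(seq_along(pieces), keep)
  net$segments <- lapply(keep, function(i) {
    geo <- seg_geometry(pieces[[i]], cs)
    list(cells = pieces[[i]], length_m = geo$length,
         sinuosity = geo$sinuosity, strahler = piece_ord[i],
         downstream = if (is.na(piece_down[i])) NA_integer_
         else remap[piece_down[i]])
  })
  net
}

#' @export
print.rh_flownet <- function(x, ...) {
  n <- length(x$segments)
  cat(sprintf("<rh_flownet> %d segments", n))
  if (n) {
    len <- sum(vapply(x$segments, `[[`, 0, "length_m"))
    cat(sprintf(", total %.1f km, orders %s", len / 1000,
                paste(sort(unique(vapply(x$segments, `[[`, 0L, "strahler"))),
                      collapse = "/")))
  }
  cat("\n")
  invisible(x)
}

#' All stream cells of a network as a mask
#'
#' @param net an `rh_flownet`.
#' @param template optional `rh_grid` supplying geometry (defaults to the
#'   network's own).
#' @return an `rh_mask`.
#' @export
flownet_mask <- function(net, template = NULL) {
  nr <- net$dim[1]; nc <- net$dim[2]
  m <- matrix(FALSE, nr, nc)
  for (s in net$segments) m[s$cells] <- TRUE
  if (is.null(template))
    mask_create(m, cell_size = net$cell_size, origin_x = net$origin_x,
                origin_y = net$origin_y)
  else mask_create(m, template = template)
}

subset_net <- function(net, keep) {
  net$segments <- net$segments[keep]
  net
}

# min distance (m) from each segment of `net` to any cell of `other_mask`
seg_min_dist <- function(net, other_mask) {
  if (!any(other_mask$member))
    return(rep(Inf, length(net$segments)))
  d <- sqrt(edt_sq(other_mask$member)) * net$cell_size
  vapply(net$segments, function(s) min(d[s$cells]), 0)
}

#' Distance of each segment to a reference network, with outlier cutoff
#'
#' Returns per-segment nearest distances to the reference flowlines plus the
#' mean + 2 SD cutoff conventionally used to discard outliers.
#'
#' @param net,reference `rh_flownet` objects on the same geometry.
#' @return list with `dist` (per segment, m), `mean`, `sd`, `cutoff`.
#' @export
reference_distance_stats <- function(net, reference) {
  d <- seg_min_dist(net, flownet_mask(reference))
  list(dist = d, mean = mean(d), sd = stats::sd(d),
       cutoff = mean(d) + 2 * stats::sd(d))
}

#' Five-rule flowline cleaning cascade
#'
#' Applies, in order: (1) drop segments lying inside waterbody interiors;
#' (2) drop long straight artifacts (length >= `min_straight_len` and
#' sinuosity <= `max_straight_sinuosity`); (3) keep segments within
#' `reference_radius` of the reference network (skipped with a warning when
#' the reference is empty); (4) keep segments with a majority of cells in
#' landform classes 6-10 and at least one cell 8-adjacent to woody wetlands;
#' (5) iteratively drop isolated short segments (< `short_len` with no other
#' retained segment within `isolation`).  The result is a pure subset of the
#' input and re-cleaning it is a no-op.
#'
#' @param net an `rh_flownet`.
#' @param waterbodies `rh_mask` of waterbody interiors.
#' @param reference `rh_flownet` of reference (coarse) flowlines.
#' @param landform categorical landform `rh_grid` (codes 1-10).
#' @param woody_wetland `rh_mask` of woody-wetland cells.
#' @param reference_radius rule-3 retention radius in meters.
#' @param min_straight_len,max_straight_sinuosity rule-2 gates.
#' @param short_len,isolation rule-5 gates (meters).
#' @return the cleaned `rh_flownet`; attribute `removal_rule` maps each input
#'   segment to the rule (1-5) that removed it, 0 if kept.
#' @export
clean_flowlines <- function(net, waterbodies, reference, landform,
                            woody_wetland, reference_radius = 3000,
                            min_straight_len = 300,
                            max_straight_sinuosity = 1.01,
                            short_len = 100, isolation = 1500) {
  nseg <- length(net$segments)
  rule <- integer(nseg)
  alive <- rep(TRUE, nseg)

  # rule 1: fully inside waterbody interiors
  for (s in seq_len(nseg)) {
    if (all(waterbodies$member[net$segments[[s]]$cells])) {
      rule[s] <- 1L; alive[s] <- FALSE
    }
  }
  # rule 2: long straight artifacts
  for (s in which(alive)) {
    sg <- net$segments[[s]]
    if (sg$length_m >= min_straight_len &&
        sg$sinuosity <= max_straight_sinuosity) {
      rule[s] <- 2L; alive[s] <- FALSE
    }
  }
  # rule 3: proximity to the reference network
  if (length(reference$segments) == 0) {
    warning("empty reference network: rule 3 skipped")
  } else {
    d <- seg_min_dist(net, flownet_mask(reference))
    for (s in which(alive)) if (d[s] > reference_radius) {
      rule[s] <- 3L; alive[s] <- FALSE
    }
  }
  # rule 4: majority landform 6-10 and adjacency to woody wetlands
  ww_adj <- woody_wetland$member
  for (dd in seq_len(8))
    ww_adj <- ww_adj | shift_mat(woody_wetland$member, D8_OFFSETS[dd, 1],
                                 D8_OFFSETS[dd, 2], fill = FALSE)
  for (s in which(alive)) {
    cells <- net$segments[[s]]$cells
    lf <- landform$values[cells]
    maj <- mean(!is.na(lf) & lf >= 6 & lf <= 10) > 0.5
    touch <- any(ww_adj[cells])
    if (!(maj && touch)) { rule[s] <- 4L; alive[s] <- FALSE }
  }
  # rule 5: isolated short segments, iterated to a fixpoint so that the
  # cascade is idempotent
  repeat {
    dropped <- FALSE
    live <- which(alive)
    for (s in live) {
      sg <- net$segments[[s]]
      if (sg$length_m >= short_len) next
      others <- setdiff(live, s)
      if (length(others) == 0) { dmin <- Inf } else {
        om <- matrix(FALSE, net$dim[1], net$dim[2])
        for (o in others) om[net$segments[[o]]$cells] <- TRUE
        dmin <- min(sqrt(edt_sq(om))[sg$cells]) * net$cell_size
      }
      if (dmin > isolation) {
        rule[s] <- 5L; alive[s] <- FALSE; dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  out <- subset_net(net, which(alive))
  attr(out, "removal_rule") <- rule
  out
}

#' Write a flowline network's segment attributes to CSV
#'
#' One row per segment (id, strahler order, length, sinuosity, endpoints);
#' cell paths go to a sidecar JSON file when `cells_json` is given.
#'
#' @param net an `rh_flownet`.
#' @param path CSV output path.
#' @param cells_json optional JSON path for the per-segment cell paths.
#' @export
flownet_write_csv <- function(net, path, cells_json = NULL) {
  df <- do.call(rbind, lapply(seq_along(net$segments), function(i) {
    s <- net$segments[[i]]
    n <- nrow(s$cells)
    data.frame(id = i, strahler_order = s$strahler, length_m = s$length_m,
               sinuosity = s$sinuosity, n_cells = n,
               head_row = s$cells[1, 1], head_col = s$cells[1, 2],
               tail_row = s$cells[n, 1], tail_col = s$cells[n, 2])
  }))
  if (is.null(df)) df <- data.frame()
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(cells_json)) {
    cells <- lapply(net$segments, function(s)
      unname(apply(s$cells, 1, function(rc) c(rc[1], rc[2]), simplify = FALSE)))
    jsonlite::write_json(cells, cells_json)
  }
  invisible(path)
}
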