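# Refinement of the continuous suitability surface into breeding habitat
# (threshold -> upper Jenks class -> isolated-patch and urban-embedded
# screens) and its extension with surrounding terrestrial habitat.

#' Binarize a suitability map at a threshold
#'
#' @param cloglog continuous `rh_grid` of suitability in (0, 1).
#' @param threshold cells with `cloglog >= threshold` become members.
#' @return an `rh_mask`.
#' @export
binarize <- function(cloglog, threshold) {
  grid_mask(cloglog, function(v) !is.na(v) & v >= threshold)
}

#' Exact two-class Jenks (Fisher) break
#'
#' Finds the split of the sorted values minimizing the within-class sum of
#' squared deviations by exhaustive evaluation with prefix sums (for two
#' classes this is the exact dynamic program).  Returns the lower edge of
#' the upper class.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return list with `break_value` (smallest member of the upper class) and
#'   `ssd` (within-class sum of squares).
#' @export
jenks_break2 <- function(values) {
  v <- sort(values[!is.na(values)])
  if (length(unique(v)) < 2) stop("need at least 2 distinct values")
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  ssd_seg <- function(i, j) {  # within-SS of v[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  best <- Inf; cut <- 1
  for (k in 1:(n - 1)) {
    if (v[k] == v[k + 1]) next  # classes must split between distinct values
    tot <- ssd_seg(1, k) + ssd_seg(k + 1, n)
    if (tot < best) { best <- tot; cut <- k }
  }
  list(break_value = v[cut + 1], ssd = best)
}

#' Keep only the upper Jenks class of suitable cells
#'
#' Bifurcates the suitability values above `threshold` into two natural
#' classes and retains the cells of the upper one.
#'
#' @param cloglog continuous suitability `rh_grid`.
#' @param threshold lower bound of the values considered.
#' @return an `rh_mask` of upper-class cells.
#' @export
jenks_upper <- function(cloglog, threshold) {
  vals <- cloglog$values[!is.na(cloglog$values) &
                           cloglog$values >= threshold]
  br <- jenks_break2(vals)
  grid_mask(cloglog, function(v) !is.na(v) & v >= br$break_value)
}

# label 8-connected components; returns a matrix of component ids (0 = empty)
label_components <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  idx <- which(member)
  if (!length(idx)) return(matrix(0L, nr, nc))
  pos <- match(seq_len(nr * nc), idx)  # cell -> vertex id
  edges <- integer(0)
  for (d in 1:4) {  # half the directions suffice for an undirected graph
    dr <- D8_OFFSETS[d, 1]; dc <- D8_OFFSETS[d, 2]
    nb <- shift_mat(member, dr, dc, fill = FALSE)
    both <- which(member & nb)
    if (!length(both)) next
    r <- ((both - 1L) %% nr) + 1L; cc <- ((both - 1L) %/% nr) + 1L
    src <- both
    dst <- (cc - dc - 1L) * nr + (r - dr)
    edges <- c(edges, rbind(pos[src], pos[dst]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, nr, nc)
  out[idx] <- comp
  out
}

#' Remove small isolated patches
#'
#' Drops 8-connected components of at most `max_cells` cells whose nearest
#' cell of any larger component is farther than `isolation` (cell-center
#' distance).
#'
#' @param mask an `rh_mask`.
#' @param max_cells largest removable patch size (default 2).
#' @param isolation removal distance in meters (default 1000).
#' @return the filtered `rh_mask`.
#' @export
drop_isolated <- function(mask, max_cells = 2, isolation = 1000) {
  lab <- label_components(mask$member)
  if (!any(lab > 0)) return(mask)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes <= max_cells)
  if (!length(small)) return(mask)
  large_mask <- mask$member & !(lab %in% small)
  keep <- mask$member
  if (!any(large_mask)) {
    # no larger patch exists: isolation is vacuously infinite
    for (s in small) keep[lab == s] <- FALSE
  } else {
    d <- sqrt(edt_sq(large_mask)) * mask$cell_size
    for (s in small) {
      if (min(d[lab == s]) > isolation) keep[lab == s] <- FALSE
    }
  }
  mask_create(keep, template = mask)
}

#' Remove habitat cells embedded in developed landscapes
#'
#' A habitat cell is dropped when more than `frac` of the cells within
#' `radius` of it (circular window, shrunk at grid edges) are developed or
#' barren.
#'
#' @param mask habitat `rh_mask`.
#' @param landcover categorical `rh_grid` on [lc_legend()] codes.
#' @param radius buffer radius in meters (default 500).
#' @param frac developed-fraction threshold (default 0.5, strict).
#' @return the filtered `rh_mask`.
#' @export
drop_urban_embedded <- function(mask, landcover, radius = 500, frac = 0.5) {
  dev <- landcover$values %in% lc_groups()$developed_or_barren
  devg <- grid_create(matrix(as.numeric(dev), nrow(landcover$values),
                             ncol(landcover$values)),
                      landcover$cell_size, landcover$origin_x,
                      landcover$origin_y)
  share <- focal_stat(devg, radius, "mean")$values
  keep <- mask$member & !(share > frac)
  mask_create(keep, template = mask)
}

#' Extend breeding habitat with surrounding terrestrial habitat
#'
#' Terrestrial habitat is every cell within `radius` of breeding habitat
#' that carries one of the open terrestrial classes (evergreen forest,
#' shrub/scrub, herbaceous) with canopy < 50% and is not itself breeding
#' habitat.
#'
#' @param breeding breeding-habitat `rh_mask` (non-empty).
#' @param landcover categorical `rh_grid`.
#' @param canopy percent canopy `rh_grid`.
#' @param radius buffer distance in meters (default 500).
#' @return an `rh_habitat`: list with `breeding`, `terrestrial`, `combined`
#'   masks and `areas_km2`.
#' @export
extend_terrestrial <- function(breeding, landcover, canopy, radius = 500) {
  if (!any(breeding$member)) stop("breeding habitat is empty")
  buf <- buffer_mask(breeding, radius)
  terr_lc <- grid_mask(landcover, lc_groups()$terrestrial)
  open <- grid_mask(canopy, function(v) !is.na(v) & v < 50)
  terrestrial <- mask_diff(mask_intersect(mask_intersect(buf, terr_lc), open),
                           breeding)
  combined <- mask_union(breeding, terrestrial)
  structure(list(breeding = breeding, terrestrial = terrestrial,
                 combined = combined,
                 areas_km2 = list(breeding = area_km2(breeding),
                                  terrestrial = area_km2(terrestrial),
                                  combined = area_km2(combined))),
            class = "rh_habitat")
}

#' @export
print.rh_habitat <- function(x, ...) {
  a <- x$areas_km2
  cat(sprintf("<rh_habitat> breeding %.4g + terrestrial %.4g = %.4g km^2\n",
              a$breeding, a$terrestrial, a$combined))
  invisible(x)
}

#' Combine published component areas into the habitat bookkeeping
#'
#' The same additive accounting used by [extend_terrestrial()], applied to
#' scalar areas (breeding and terrestrial habitat are disjoint by
#' construction, so the combined area is their sum).
#'
#' @param breeding_km2,terrestrial_km2 component areas in km^2.
#' @return list with the component and combined areas.
#' @export
habitat_area_summary <- function(breeding_km2, terrestrial_km2) {
  list(breeding_km2 = breeding_km2, terrestrial_km2 = terrestrial_km2,
       combined_km2 = breeding_km2 + terrestrial_km2)
}

#' Full refinement cascade from suitability map to habitat model
#'
#' Threshold, upper Jenks class, isolated-patch screen, urban-embedded
#' screen, then the terrestrial extension.  Each mask step shrinks its
#' input, and the two screens are jointly idempotent.
#'
#' @param cloglog suitability `rh_grid`.
#' @param threshold binary threshold (usually the ESS threshold).
#' @param landcover,canopy legend/canopy grids.
#' @param max_cells,isolation [drop_isolated()] parameters.
#' @param urban_radius,urban_frac [drop_urban_embedded()] parameters.
#' @param terrestrial_radius [extend_terrestrial()] buffer.
#' @return an `rh_habitat`; attribute `steps` holds per-step areas.
#' @export
delineate_habitat <- function(cloglog, threshold, landcover, canopy,
                              max_cells = 2, isolation = 1000,
                              urban_radius = 500, urban_frac = 0.5,
                              terrestrial_radius = 500) {
  b0 <- binarize(cloglog, threshold)
  b1 <- jenks_upper(cloglog, threshold)
  b2 <- drop_isolated(b1, max_cells, isolation)
  b3 <- drop_urban_embedded(b2, landcover, urban_radius, urban_frac)
  out <- extend_terrestrial(b3, landcover, canopy, terrestrial_radius)
  attr(out, "steps") <- list(binary = area_km2(b0), jenks = area_km2(b1),
                             isolated = area_km2(b2), urban = area_km2(b3))
  out
}
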