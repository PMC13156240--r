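# Conservation gap analysis: protected-area coverage, adjacent-land-use
# exposure, and projected-urbanization threat of the final habitat model.

#' Protected-area coverage of habitat, per region
#'
#' @param habitat habitat `rh_mask`.
#' @param protected protected-area `rh_mask`.
#' @param regions categorical `rh_grid` of region labels, or NULL for a
#'   single "total" region.
#' @return data.frame with region, habitat_km2, protected_km2,
#'   protected_pct, unprotected_km2 (a "total" row is always present).
#' @export
protected_coverage <- function(habitat, protected, regions = NULL) {
  stopifnot_same_geometry(habitat, protected)
  cell <- habitat$cell_size^2 / 1e6
  lab <- if (is.null(regions)) matrix(1, nrow(habitat$member),
                                      ncol(habitat$member))
  else regions$values
  labs <- sort(unique(lab[habitat$member & !is.na(lab)]))
  row_for <- function(sel, name) {
    h <- sum(sel) * cell
    p <- sum(sel & protected$member) * cell
    data.frame(region = name, habitat_km2 = h, protected_km2 = p,
               protected_pct = if (h > 0) 100 * p / h else 0,
               unprotected_km2 = h - p)
  }
  out <- do.call(rbind, lapply(labs, function(l)
    row_for(habitat$member & !is.na(lab) & lab == l, as.character(l))))
  rbind(out, row_for(habitat$member, "total"))
}

#' Adjacent land-use exposure within a one-cell buffer ring
#'
#' Measures indirect threat from development, agriculture, and plantations
#' next to habitat.  Two views are reported for each class: `ring_pct`, the
#' share of the one-cell buffer ring covered by the class, and
#' `habitat_adjacent_pct` / `habitat_adjacent_km2`, the share of habitat
#' cells with at least one 8-neighbor ring cell of the class (the view
#' comparable to a habitat-area-based table).
#'
#' @param habitat habitat `rh_mask`.
#' @param landcover categorical `rh_grid` on [lc_legend()] codes.
#' @param plantations `rh_mask` of tree plantations (silviculture is not an
#'   NLCD class, so it arrives as its own layer).
#' @param buffer ring width in meters (default 60, one cell).
#' @return data.frame with one row per exposure class.
#' @export
adjacency_exposure <- function(habitat, landcover, plantations,
                               buffer = 60) {
  stopifnot_same_geometry(habitat, landcover)
  grp <- lc_groups()
  ring <- mask_diff(buffer_mask(habitat, buffer), habitat)
  cell <- habitat$cell_size^2 / 1e6
  n_ring <- sum(ring$member)
  h_area <- area_km2(habitat)
  class_masks <- list(
    development = !is.na(landcover$values) &
      matrix(landcover$values %in% grp$developed, nrow(landcover$values)),
    agriculture = !is.na(landcover$values) &
      matrix(landcover$values %in% grp$agriculture, nrow(landcover$values)),
    plantation = plantations$member)
  do.call(rbind, lapply(names(class_masks), function(nm) {
    cm <- class_masks[[nm]]
    ring_hit <- sum(ring$member & cm)
    # habitat cells adjacent to a ring cell of this class
    adj <- matrix(FALSE, nrow(cm), ncol(cm))
    ring_cm <- ring$member & cm
    for (d in seq_len(8))
      adj <- adj | shift_mat(ring_cm, D8_OFFSETS[d, 1], D8_OFFSETS[d, 2],
                             fill = FALSE)
    h_adj <- sum(habitat$member & adj)
    data.frame(class = nm,
               ring_pct = if (n_ring > 0) 100 * ring_hit / n_ring else 0,
               habitat_adjacent_km2 = h_adj * cell,
               habitat_adjacent_pct = if (h_area > 0)
                 100 * h_adj * cell / h_area else 0)
  }))
}

#' Projected-urbanization threat to unprotected habitat
#'
#' Urbanization probabilities inside protected areas are zeroed first (they
#' are not expected to develop); the remaining projected cells are
#' intersected with unprotected habitat and split into the < 50% and >= 50%
#' probability classes plus their total.
#'
#' @param habitat habitat `rh_mask`.
#' @param protected protected-area `rh_mask`.
#' @param sleuth `rh_grid` of development probability (0-100 or 0-1;
#'   cells with probability 0 or NA carry no projection).
#' @param split class boundary on the percent scale (default 50).
#' @return data.frame with class (`p_lt50`, `p_ge50`, `total`), area_km2,
#'   pct_of_unprotected, pct_of_habitat.
#' @export
urbanization_threat <- function(habitat, protected, sleuth, split = 50) {
  stopifnot_same_geometry(habitat, sleuth)
  p <- sleuth$values
  if (max(p, na.rm = TRUE) <= 1) p <- p * 100   # accept the 0-1 scale
  p[protected$member] <- 0                      # omit protected projections
  cell <- habitat$cell_size^2 / 1e6
  unprot <- habitat$member & !protected$member
  unprot_km2 <- sum(unprot) * cell
  hab_km2 <- area_km2(habitat)
  proj <- !is.na(p) & p > 0
  a_lt <- sum(unprot & proj & p < split) * cell
  a_ge <- sum(unprot & proj & p >= split) * cell
  mk <- function(cl, a) data.frame(
    class = cl, area_km2 = a,
    pct_of_unprotected = if (unprot_km2 > 0) 100 * a / unprot_km2 else 0,
    pct_of_habitat = if (hab_km2 > 0) 100 * a / hab_km2 else 0)
  rbind(mk("p_lt50", a_lt), mk("p_ge50", a_ge), mk("total", a_lt + a_ge))
}

#' Scalar gap arithmetic on published areas
#'
#' The bookkeeping used by [gap_summary()], exposed for area-level inputs:
#' protected percentage, unprotected remainder, and the projected-development
#' shares of unprotected and total habitat.
#'
#' @param habitat_km2,protected_km2,projected_km2 areas in km^2.
#' @return list of derived areas and percentages.
#' @export
gap_arithmetic <- function(habitat_km2, protected_km2, projected_km2) {
  unprotected <- habitat_km2 - protected_km2
  list(habitat_km2 = habitat_km2,
       protected_km2 = protected_km2,
       protected_pct = 100 * protected_km2 / habitat_km2,
       unprotected_km2 = unprotected,
       projected_km2 = projected_km2,
       projected_pct_of_unprotected = 100 * projected_km2 / unprotected,
       projected_pct_of_habitat = 100 * projected_km2 / habitat_km2)
}

#' Full gap report for a habitat model
#'
#' Assembles protected coverage, adjacency exposure, and urbanization threat
#' for each habitat component (breeding, terrestrial, combined), per region
#' and in total, and cross-checks the internal arithmetic.
#'
#' @param habitat_model an `rh_habitat`.
#' @param protected protected-area `rh_mask`.
#' @param sleuth urbanization-probability `rh_grid`.
#' @param landcover categorical `rh_grid`.
#' @param plantations plantation `rh_mask`.
#' @param regions optional categorical region `rh_grid`.
#' @param tol_pct consistency tolerance in percent (default 0.5).
#' @return an `rh_gap_report` list with one block per component.
#' @export
gap_summary <- function(habitat_model, protected, sleuth, landcover,
                        plantations, regions = NULL, tol_pct = 0.5) {
  comps <- list(breeding = habitat_model$breeding,
                terrestrial = habitat_model$terrestrial,
                combined = habitat_model$combined)
  out <- lapply(names(comps), function(nm) {
    hab <- comps[[nm]]
    if (!any(hab$member))
      return(list(component = nm, empty = TRUE))
    pc <- protected_coverage(hab, protected, regions)
    ae <- adjacency_exposure(hab, landcover, plantations)
    ut <- urbanization_threat(hab, protected, sleuth)
    tot <- pc[pc$region == "total", ]
    # internal consistency: percent = 100 * part / whole; classes add up
    stopifnot_consistent <- function(lhs, rhs, what) {
      if (abs(lhs - rhs) > tol_pct)
        stop(sprintf("gap_summary inconsistency in %s (%s): %.3f vs %.3f",
                     nm, what, lhs, rhs))
    }
    stopifnot_consistent(tot$protected_pct,
                         100 * tot$protected_km2 / tot$habitat_km2,
                         "protected_pct")
    stopifnot_consistent(ut$area_km2[3], ut$area_km2[1] + ut$area_km2[2],
                         "threat classes")
    reg_sum <- sum(pc$habitat_km2[pc$region != "total"])
    cellarea <- hab$cell_size^2 / 1e6
    if (!is.null(regions) &&
        abs(reg_sum - tot$habitat_km2) > cellarea * nrow(pc))
      stop("regional areas do not add up to the total")
    list(component = nm, protected = pc, adjacency = ae, threat = ut,
         arithmetic = gap_arithmetic(tot$habitat_km2, tot$protected_km2,
                                     ut$area_km2[3]))
  })
  names(out) <- names(comps)
  structure(out, class = "rh_gap_report")
}

#' @export
print.rh_gap_report <- function(x, ...) {
  for (nm in names(x)) {
    b <- x[[nm]]
    if (isTRUE(b$empty)) { cat(sprintf("%s: empty\n", nm)); next }
    a <- b$arithmetic
    cat(sprintf("%s: %.4g km^2, %.0f%% protected, %.0f%% of unprotected projected developed\n",
                nm, a$habitat_km2, a$protected_pct,
                a$projected_pct_of_unprotected))
  }
  invisible(x)
}

#' Write a gap report to CSV (one file per block) and JSON
#'
#' @param report an `rh_gap_report`.
#' @param dir output directory.
#' @export
gap_write <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    b <- report[[nm]]
    if (isTRUE(b$empty)) next
    utils::write.csv(b$protected,
                     file.path(dir, paste0("protected_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(b$adjacency,
                     file.path(dir, paste0("adjacency_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(b$threat,
                     file.path(dir, paste0("threat_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(lapply(report, function(b)
    if (isTRUE(b$empty)) b else b["arithmetic"]),
    file.path(dir, "gap_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
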