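# Assembly of the 12-variable covariate stack, collinearity screening,
# focal-radius selection by information value, and land-cover change
# accounting.

#' Land-cover legend (NLCD-like, 15 classes)
#'
#' Named integer codes for the land-cover classes used throughout the
#' package, with the class groupings that drive covariates and filters.
#'
#' @return named integer vector of class codes.
#' @export
lc_legend <- function() {
  c(open_water = 11L, developed_open = 21L, developed_low = 22L,
    developed_medium = 23L, developed_high = 24L, barren = 31L,
    deciduous_forest = 41L, evergreen_forest = 42L, mixed_forest = 43L,
    shrub_scrub = 52L, herbaceous = 71L, hay_pasture = 81L,
    cultivated_crops = 82L, woody_wetlands = 90L, emergent_wetlands = 95L)
}

#' @rdname lc_legend
#' @export
lc_groups <- function() {
  lg <- lc_legend()
  list(
    developed = unname(lg[c("developed_low", "developed_medium",
                            "developed_high")]),
    developed_or_barren = unname(lg[c("developed_low", "developed_medium",
                                      "developed_high", "barren")]),
    agriculture = unname(lg[c("hay_pasture", "cultivated_crops")]),
    terrestrial = unname(lg[c("evergreen_forest", "shrub_scrub",
                              "herbaceous")]))
}

#' Names of the 12 covariate layers
#' @export
covariate_names <- function() {
  c("slope", "tpi", "landform", "conductivity", "ph", "pct_sand",
    "dist_stream", "dist_terrestrial", "pct_developed", "pct_agriculture",
    "temp_march", "precip_march")
}

# paint per-watershed class percentages back onto cells
watershed_pct <- function(landcover, watersheds, codes) {
  lc <- landcover$values; ws <- watersheds$values
  ok <- !is.na(lc) & !is.na(ws)
  tot <- tapply(ok, ws, sum)
  hit <- tapply(ok & (lc %in% codes), ws, sum)
  pct <- 100 * hit / pmax(tot, 1)
  out <- matrix(NA_real_, nrow(lc), ncol(lc))
  out[!is.na(ws)] <- pct[as.character(ws[!is.na(ws)])]
  grid_create(out, landcover$cell_size, landcover$origin_x,
              landcover$origin_y)
}

#' Build the 12-layer covariate stack
#'
#' Derives, on a shared 60-m geometry: focal-mean slope and TPI and the
#' geomorphon landform grid from the DEM; focal-mean soil attributes;
#' distance to the cleaned headwater network; distance to open-canopy
#' terrestrial classes (evergreen forest, shrub/scrub, herbaceous with
#' canopy < 50\%); percent developed and percent agriculture painted per
#' subwatershed; and the pass-through climate layers.
#'
#' @param dem elevation `rh_grid`.
#' @param landcover categorical `rh_grid` with [lc_legend()] codes.
#' @param canopy percent tree-canopy `rh_grid` (0-100).
#' @param soils named list of `rh_grid`s: `conductivity`, `ph`, `pct_sand`.
#' @param climate named list of `rh_grid`s: `temp_march`, `precip_march`.
#' @param net cleaned `rh_flownet` (orders 1-2).
#' @param watersheds categorical `rh_grid` of subwatershed labels.
#' @param radius focal radius in meters (default 120).
#' @param landform optional precomputed landform grid (else derived).
#' @return an `rh_stack`: named list of `rh_grid`s plus metadata.
#' @export
build_stack <- function(dem, landcover, canopy, soils, climate, net,
                        watersheds, radius = 120, landform = NULL) {
  for (nm in c("conductivity", "ph", "pct_sand"))
    if (is.null(soils[[nm]])) stop("missing soil layer: ", nm)
  for (nm in c("temp_march", "precip_march"))
    if (is.null(climate[[nm]])) stop("missing climate layer: ", nm)
  grp <- lc_groups()
  terr <- grid_mask(landcover, grp$terrestrial)
  open_canopy <- grid_mask(canopy, function(v) !is.na(v) & v < 50)
  terr_open <- mask_intersect(terr, open_canopy)
  layers <- list(
    slope = slope(dem, radius),
    tpi = tpi(dem, radius),
    landform = if (is.null(landform)) geomorphons(dem) else landform,
    conductivity = focal_stat(soils$conductivity, radius, "mean"),
    ph = focal_stat(soils$ph, radius, "mean"),
    pct_sand = focal_stat(soils$pct_sand, radius, "mean"),
    dist_stream = distance_to(flownet_mask(net, template = dem)),
    dist_terrestrial = if (any(terr_open$member)) distance_to(terr_open)
    else grid_create(matrix(Inf, nrow(dem$values), ncol(dem$values)),
                     dem$cell_size, dem$origin_x, dem$origin_y),
    pct_developed = watershed_pct(landcover, watersheds, grp$developed),
    pct_agriculture = watershed_pct(landcover, watersheds, grp$agriculture),
    temp_march = climate$temp_march,
    precip_march = climate$precip_march)
  structure(list(layers = layers, radius = radius,
                 categorical = "landform"),
            class = "rh_stack")
}

#' @export
print.rh_stack <- function(x, ...) {
  cat(sprintf("<rh_stack> %d layers (%s categorical), focal radius %g m\n",
              length(x$layers), paste(x$categorical, collapse = ","),
              x$radius))
  invisible(x)
}

#' Extract covariate values at point locations or cells
#'
#' @param stack an `rh_stack`.
#' @param x,y world coordinates, or `cells` a (row, col) matrix.
#' @param cells optional cell matrix overriding `x`/`y`.
#' @return data.frame with one column per layer.
#' @export
stack_extract <- function(stack, x = NULL, y = NULL, cells = NULL) {
  g1 <- stack$layers[[1]]
  if (is.null(cells)) cells <- cell_at(g1, x, y)
  out <- lapply(stack$layers, function(g) g$values[cells])
  as.data.frame(out)
}

#' Pairwise collinearity screen
#'
#' Pearson |r| for continuous-continuous pairs and the ANOVA correlation
#' ratio eta (square root of the between-class share of variance) for
#' categorical-continuous pairs, computed on a presence+background sample.
#' Pairs at or above `threshold` are flagged; eta and eta^2 are both
#' reported.  Zero-variance layers are excluded with a warning.
#'
#' @param sample data.frame of covariate values (as from [stack_extract()]).
#' @param categorical names of categorical columns.
#' @param threshold flagging threshold on |r| and eta (default 0.70).
#' @return data.frame with var1, var2, statistic, value, value_squared,
#'   flagged.
#' @export
collinearity_screen <- function(sample, categorical = "landform",
                                threshold = 0.70) {
  if (nrow(sample) < 30) stop("need a sample of at least 30 rows")
  sample <- sample[stats::complete.cases(sample), , drop = FALSE]
  keep <- vapply(names(sample), function(nm) {
    v <- sample[[nm]]
    ok <- if (nm %in% categorical) length(unique(v)) > 1
    else stats::var(v) > 0
    if (!ok) warning("zero-variance layer excluded: ", nm)
    ok
  }, TRUE)
  sample <- sample[keep]
  nms <- names(sample)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    a <- nms[i]; b <- nms[j]
    a_cat <- a %in% categorical; b_cat <- b %in% categorical
    if (a_cat && b_cat) next
    if (!a_cat && !b_cat) {
      v <- abs(stats::cor(sample[[a]], sample[[b]]))
      rows[[length(rows) + 1]] <- data.frame(
        var1 = a, var2 = b, statistic = "pearson_r", value = v,
        value_squared = v^2, flagged = v >= threshold)
    } else {
      gvar <- if (a_cat) sample[[a]] else sample[[b]]
      cvar <- if (a_cat) sample[[b]] else sample[[a]]
      eta <- correlation_ratio(gvar, cvar)
      rows[[length(rows) + 1]] <- data.frame(
        var1 = a, var2 = b, statistic = "eta", value = eta,
        value_squared = eta^2, flagged = eta >= threshold)
    }
  }
  do.call(rbind, rows)
}

#' ANOVA correlation ratio eta between a grouping and a continuous variable
#'
#' `eta^2` equals the between-group sum of squares over the total sum of
#' squares (the R^2 of a one-way ANOVA on the same grouping).
#'
#' @param groups class codes.
#' @param values continuous values.
#' @return eta in \[0, 1\].
#' @export
correlation_ratio <- function(groups, values) {
  mu <- mean(values)
  ss_tot <- sum((values - mu)^2)
  if (ss_tot == 0) return(0)
  mg <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ss_between <- sum(ng * (mg - mu)^2)
  sqrt(ss_between / ss_tot)
}

#' Weight of evidence and information value of one variable
#'
#' Values are decile-binned over the pooled presence+background sample; each
#' bin's weight of evidence is `ln((p_i/P)/(b_i/B))` with zero cells smoothed
#' by adding 0.5 to both counts, and the information value is
#' `sum((p_i/P - b_i/B) * WoE_i)`.
#'
#' @param pres,bg numeric covariate values at presences / background.
#' @param bins number of quantile bins (default 10).
#' @return list with the per-bin table and `iv`.
#' @export
woe_iv <- function(pres, bg, bins = 10) {
  pres <- pres[!is.na(pres)]; bg <- bg[!is.na(bg)]
  if (!length(pres)) stop("no presence values")
  pooled <- c(pres, bg)
  brk <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = bins + 1)))
  if (length(brk) < 3) return(list(table = NULL, iv = 0))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  pcut <- cut(pres, brk); bcut <- cut(bg, brk)
  p <- as.numeric(table(pcut)); b <- as.numeric(table(bcut))
  zero <- p == 0 | b == 0
  p[zero] <- p[zero] + 0.5; b[zero] <- b[zero] + 0.5
  pr <- p / sum(p); br <- b / sum(b)
  woe <- log(pr / br)
  list(table = data.frame(bin = levels(pcut), n_pres = p, n_bg = b,
                          woe = woe),
       iv = sum((pr - br) * woe))
}

#' Select the focal radius by total information value
#'
#' For each candidate radius, sums the information value of every
#' neighborhood-derived continuous variable over the presence/background
#' sample and returns the radius with the largest total.
#'
#' @param stacks named list of `rh_stack`s, names are radii in meters.
#' @param pres_cells,bg_cells (row, col) matrices of presences / background.
#' @param variables neighborhood-derived variables to score.
#' @return list with `radius` (numeric winner) and the per-radius IV table.
#' @export
select_radius <- function(stacks, pres_cells, bg_cells,
                          variables = c("slope", "tpi", "conductivity",
                                        "ph", "pct_sand")) {
  if (length(stacks) < 2) stop("need at least 2 candidate stacks")
  if (is.null(pres_cells) || nrow(pres_cells) == 0)
    stop("no presences supplied")
  tab <- lapply(names(stacks), function(r) {
    st <- stacks[[r]]
    ivs <- vapply(variables, function(v) {
      woe_iv(st$layers[[v]]$values[pres_cells],
             st$layers[[v]]$values[bg_cells])$iv
    }, 0)
    data.frame(radius = as.numeric(r), variable = variables, iv = ivs)
  })
  tab <- do.call(rbind, tab)
  tot <- tapply(tab$iv, tab$radius, sum)
  list(radius = as.numeric(names(tot))[which.max(tot)], table = tab,
       total = tot)
}

#' Relative-percentage-area change between two epochs
#'
#' Works from per-class total areas: `delta_relpct` for class c is
#' `100 * (A_c,t2 / sum(A_t2) - A_c,t1 / sum(A_t1))` and `delta_km2` is the
#' plain area difference.  Relative changes sum to zero by construction.
#'
#' @param areas_t1,areas_t2 named numeric vectors of per-class areas (km^2)
#'   on the same legend.
#' @return data.frame with class, area_t1, area_t2, delta_km2, delta_relpct.
#' @export
area_change_table <- function(areas_t1, areas_t2) {
  if (!identical(sort(names(areas_t1)), sort(names(areas_t2))))
    stop("legend mismatch between epochs")
  areas_t2 <- areas_t2[names(areas_t1)]
  data.frame(
    class = names(areas_t1),
    area_t1 = unname(areas_t1), area_t2 = unname(areas_t2),
    delta_km2 = unname(areas_t2 - areas_t1),
    delta_relpct = unname(100 * (areas_t2 / sum(areas_t2) -
                                   areas_t1 / sum(areas_t1))),
    row.names = NULL)
}

#' Land-cover change between two categorical grids
#'
#' Tabulates per-class areas on both grids and delegates the change
#' arithmetic to [area_change_table()].
#'
#' @param lc_t1,lc_t2 categorical `rh_grid`s with a shared legend/geometry.
#' @return the change data.frame.
#' @export
landcover_change <- function(lc_t1, lc_t2) {
  stopifnot_same_geometry(lc_t1, lc_t2)
  cell_area <- lc_t1$cell_size^2 / 1e6
  classes <- sort(unique(c(lc_t1$values[!is.na(lc_t1$values)],
                           lc_t2$values[!is.na(lc_t2$values)])))
  count <- function(g) vapply(classes, function(cl)
    sum(g$values == cl, na.rm = TRUE), 0) * cell_area
  a1 <- stats::setNames(count(lc_t1), classes)
  a2 <- stats::setNames(count(lc_t2), classes)
  area_change_table(a1, a2)
}

#' Flag occurrence records whose land-cover class changed across epochs
#'
#' @param records occurrence data.frame (retained rows are evaluated).
#' @param lc_epochs named list of categorical `rh_grid`s, in epoch order.
#' @return data.frame with one class column per epoch and `changed`.
#' @export
occurrence_change_flags <- function(records, lc_epochs) {
  if (length(lc_epochs) < 2) stop("need at least 2 epochs")
  r <- occ_retained(occ_validate(records))
  g1 <- lc_epochs[[1]]
  rc <- cell_at(g1, r$x, r$y)
  seqs <- vapply(lc_epochs, function(g) g$values[rc], numeric(nrow(r)))
  if (nrow(r) == 1) seqs <- matrix(seqs, nrow = 1)
  colnames(seqs) <- names(lc_epochs) %||% paste0("epoch", seq_along(lc_epochs))
  changed <- apply(seqs, 1, function(v) length(unique(v[!is.na(v)])) > 1)
  cbind(r[c("x", "y", "year", "life_stage")], as.data.frame(seqs),
        changed = changed)
}
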