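# Occurrence record cleaning, downslope snapping to stream reaches, and
# one-record-per-reach spatial thinning.
#
# Records travel as a data.frame with columns x, y (m), year (int),
# life_stage ("nymph" | "adult"), source (free tag), reach_id (int or NA),
# status ("retained" or "dropped:<reason>").  Every drop keeps its row, so
# the full provenance of the pipeline is auditable.

occ_validate <- function(records) {
  need <- c("x", "y", "year", "life_stage", "source")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("occurrence records lack columns: ", paste(missing, collapse = ", "))
  if (!all(records$life_stage %in% c("nymph", "adult")))
    stop("life_stage must be 'nymph' or 'adult'")
  if (is.null(records$reach_id)) records$reach_id <- NA_integer_
  if (is.null(records$status)) records$status <- "retained"
  records
}

occ_retained <- function(records) records[records$status == "retained", ]

# canonical ordering so the pipeline is stable under input shuffling
occ_canonical_order <- function(records) {
  records[order(records$x, records$y, records$year, records$life_stage,
                records$source), , drop = FALSE]
}

#' Clean occurrence records
#'
#' Removes exact duplicates (same x, y, year, life_stage; the first in
#' canonical order is kept) and drops records falling outside the study-area
#' mask.  Dropped rows stay in the output with a reason in `status`.
#'
#' @param records occurrence data.frame (see [occ_pipeline()]).
#' @param study_mask `rh_mask` of the study area, or NULL to skip the
#'   containment check.
#' @return the records with `status` updated.
#' @export
occ_clean <- function(records, study_mask = NULL) {
  records <- occ_validate(records)
  records <- occ_canonical_order(records)
  key <- paste(records$x, records$y, records$year, records$life_stage)
  dup <- duplicated(key) & records$status == "retained"
  records$status[dup] <- "dropped:duplicate"
  if (!is.null(study_mask)) {
    rc <- cell_at(study_mask, records$x, records$y)
    inside <- !is.na(rc[, 1]) & study_mask$member[rc]
    out <- !inside & records$status == "retained"
    records$status[out] <- "dropped:out_of_area"
  }
  records
}

# data.frame of (row, col, reach) for all cells of a network
net_reach_cells <- function(net) {
  if (length(net$segments) == 0)
    return(data.frame(row = integer(), col = integer(), reach = integer()))
  do.call(rbind, lapply(seq_along(net$segments), function(i)
    data.frame(row = net$segments[[i]]$cells[, 1],
               col = net$segments[[i]]$cells[, 2], reach = i)))
}

#' Snap adult records downslope onto the nearest stream reach
#'
#' Adults are moved to the nearest stream cell that is within `max_dist` and
#' not higher in elevation than the record's own cell ("downslope"); ties on
#' distance resolve to the lower cell, then the smaller reach id.  Adults
#' with no qualifying cell are dropped.  Nymphs keep their coordinates and
#' are assigned the nearest reach within `max_dist`.
#'
#' @param records cleaned occurrence data.frame.
#' @param net a cleaned `rh_flownet` whose segments define the reaches.
#' @param dem elevation `rh_grid`.
#' @param max_dist snapping radius in meters (default 300).
#' @return records with `reach_id`, updated coordinates for moved adults,
#'   and drop reasons `dropped:no_reach` / `dropped:off_grid`.
#' @export
snap_adults <- function(records, net, dem, max_dist = 300) {
  records <- occ_validate(records)
  cells <- net_reach_cells(net)
  live <- which(records$status == "retained")
  if (nrow(cells) == 0) {
    records$status[live] <- "dropped:no_reach"
    return(records)
  }
  cxy <- cell_center_xy(dem, cells$row, cells$col)
  celev <- dem$values[cbind(cells$row, cells$col)]
  for (i in live) {
    rc <- cell_at(dem, records$x[i], records$y[i])
    if (is.na(rc[1])) { records$status[i] <- "dropped:off_grid"; next }
    relev <- dem$values[rc]
    d <- sqrt((cxy[, 1] - records$x[i])^2 + (cxy[, 2] - records$y[i])^2)
    ok <- d <= max_dist
    if (records$life_stage[i] == "adult") ok <- ok & celev <= relev + 1e-9
    if (!any(ok)) { records$status[i] <- "dropped:no_reach"; next }
    cand <- which(ok)
    cand <- cand[order(d[cand], celev[cand], cells$reach[cand])]
    best <- cand[1]
    records$reach_id[i] <- cells$reach[best]
    if (records$life_stage[i] == "adult") {
      records$x[i] <- cxy[best, 1]
      records$y[i] <- cxy[best, 2]
    }
  }
  records
}

#' Thin to one record per stream reach
#'
#' Keeps a single record per `reach_id`: nymphs are preferred over adults;
#' ties within a life stage are broken uniformly at random under `seed`
#' (after canonical ordering, so the outcome does not depend on input row
#' order).
#'
#' @param records snapped occurrence data.frame.
#' @param seed integer RNG seed for the tie-break.
#' @return records with redundant rows marked `dropped:thinned`.
#' @export
thin_per_reach <- function(records, seed = 1) {
  records <- occ_validate(records)
  records <- occ_canonical_order(records)
  live <- which(records$status == "retained")
  if (any(is.na(records$reach_id[live])))
    stop("all retained records must carry a reach_id before thinning")
  with_seed(seed, {
    for (reach in sort(unique(records$reach_id[live]))) {
      rows <- live[records$reach_id[live] == reach]
      if (length(rows) <= 1) next
      nymphs <- rows[records$life_stage[rows] == "nymph"]
      pool <- if (length(nymphs)) nymphs else rows
      keep <- pool[sample.int(length(pool), 1)]
      records$status[setdiff(rows, keep)] <- "dropped:thinned"
    }
  })
  records
}

#' Nearest-neighbor distance summary of retained records
#'
#' @param records occurrence data.frame with >= 2 retained rows.
#' @return list with `mean_m` and `se_m` (sd / sqrt(n)) of the per-record
#'   nearest-neighbor Euclidean distances.
#' @export
nn_summary <- function(records) {
  r <- occ_retained(occ_validate(records))
  if (nrow(r) < 2) stop("need at least 2 retained records")
  d <- as.matrix(stats::dist(cbind(r$x, r$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  list(mean_m = mean(nn), se_m = stats::sd(nn) / sqrt(length(nn)))
}

#' Run the full occurrence pipeline
#'
#' [occ_clean()], [snap_adults()], [thin_per_reach()] in sequence, with a
#' count log of each stage.
#'
#' @inheritParams occ_clean
#' @inheritParams snap_adults
#' @inheritParams thin_per_reach
#' @param verbose print per-stage retention counts.
#' @return the processed records.
#' @export
occ_pipeline <- function(records, study_mask, net, dem, max_dist = 300,
                         seed = 1, verbose = FALSE) {
  n0 <- nrow(records)
  records <- occ_clean(records, study_mask)
  n1 <- sum(records$status == "retained")
  records <- snap_adults(records, net, dem, max_dist)
  n2 <- sum(records$status == "retained")
  records <- thin_per_reach(records, seed)
  n3 <- sum(records$status == "retained")
  if (verbose)
    message(sprintf("occurrences: %d in -> %d clean -> %d snapped -> %d thinned",
                    n0, n1, n2, n3))
  records
}

#' Read / write occurrence records as CSV
#'
#' @param records occurrence data.frame.
#' @param path file path.
#' @export
occ_write_csv <- function(records, path) {
  utils::write.csv(occ_validate(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname occ_write_csv
#' @export
occ_read_csv <- function(path) {
  occ_validate(utils::read.csv(path, stringsAsFactors = FALSE))
}
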