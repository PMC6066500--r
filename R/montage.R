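# Electrode layouts, neighbor graphs, and named ROI lead sets.

#' Build a synthetic hexagonal-grid montage
#'
#' Constructs a dense centered hexagonal electrode layout used as a synthetic
#' stand-in for a high-density net. The grid has `n_rings` concentric rings
#' (ring 1 is the single center lead), giving `1 + 3*r*(r-1)` leads for
#' `r = n_rings`. Interior leads have exactly 6 neighbors; edge leads fewer.
#' Inter-lead spacing is 1 in arbitrary head units.
#'
#' @param n_rings number of rings including the center lead; must be >= 2.
#' @param seed_label label given to the center lead (default `"C3"`), so that
#'   seed-based ROI construction has a guaranteed anchor.
#' @return an object of class `fpcoh_montage`: list with `lead_ids`,
#'   `positions` (n x 2 matrix, rownames = lead ids) and `adjacency`
#'   (symmetric logical matrix).
#' @export
build_synthetic_montage <- function(n_rings, seed_label = "C3") {
  if (!is.numeric(n_rings) || length(n_rings) != 1L || n_rings < 2)
    stop("n_rings must be a single integer >= 2")
  n_rings <- as.integer(n_rings)
  # axial hex coordinates: walk each ring counter-clockwise
  dirs <- matrix(c(1, 0, 0, 1, -1, 1, -1, 0, 0, -1, 1, -1),
                 ncol = 2, byrow = TRUE)
  qr <- matrix(0, nrow = 1, ncol = 2)
  for (r in seq_len(n_rings - 1L)) {
    pos <- c(r, 0)
    ring <- matrix(0, nrow = 6L * r, ncol = 2)
    k <- 1L
    for (d in 1:6) {
      step <- dirs[c(3, 4, 5, 6, 1, 2)[d], ]
      for (s in seq_len(r)) {
        ring[k, ] <- pos
        pos <- pos + step
        k <- k + 1L
      }
    }
    qr <- rbind(qr, ring)
  }
  xy <- cbind(qr[, 1] + qr[, 2] / 2, qr[, 2] * sqrt(3) / 2)
  n <- nrow(xy)
  ids <- c(seed_label, sprintf("E%03d", seq_len(n)[-1L]))
  rownames(xy) <- ids
  colnames(xy) <- c("x", "y")
  d <- as.matrix(stats::dist(xy))
  adj <- d > 0 & d < 1.001
  dimnames(adj) <- list(ids, ids)
  structure(list(lead_ids = ids, positions = xy, adjacency = adj),
            class = "fpcoh_montage")
}

#' Build a montage from lead positions
#'
#' For user-supplied layouts the neighbor graph is derived from geometry:
#' two leads are neighbors when their distance is at most `neighbor_factor`
#' times the smallest inter-lead distance.
#'
#' @param positions data frame or matrix with columns `lead_id`, `x`, `y`
#'   (optionally `z`), or a numeric matrix with rownames as lead ids.
#' @param neighbor_factor multiplier on the minimum inter-lead distance that
#'   defines adjacency (default 1.2).
#' @return `fpcoh_montage`
#' @export
montage_from_positions <- function(positions, neighbor_factor = 1.2) {
  if (is.data.frame(positions)) {
    ids <- as.character(positions$lead_id)
    cols <- intersect(c("x", "y", "z"), names(positions))
    xy <- as.matrix(positions[, cols, drop = FALSE])
    rownames(xy) <- ids
  } else {
    xy <- as.matrix(positions)
    ids <- rownames(xy)
  }
  if (is.null(ids) || anyNA(ids)) stop("every lead needs an id")
  if (anyDuplicated(ids)) stop("duplicate lead ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(xy)) stop("every lead needs a complete position")
  d <- as.matrix(stats::dist(xy))
  dmin <- min(d[d > 0])
  adj <- d > 0 & d <= neighbor_factor * dmin
  dimnames(adj) <- list(ids, ids)
  structure(list(lead_ids = ids, positions = xy, adjacency = adj),
            class = "fpcoh_montage")
}

#' Read a montage from a CSV file (columns lead_id,x,y[,z])
#' @param path CSV path
#' @param neighbor_factor passed to [montage_from_positions()]
#' @return `fpcoh_montage`
#' @export
read_montage_csv <- function(path, neighbor_factor = 1.2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lead_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("montage CSV needs columns lead_id,x,y")
  montage_from_positions(df, neighbor_factor)
}

#' Write a montage to CSV
#' @param montage `fpcoh_montage`
#' @param path output CSV path
#' @export
write_montage_csv <- function(montage, path) {
  df <- data.frame(lead_id = montage$lead_ids,
                   montage$positions, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Neighbor labels of a lead
#' @param montage `fpcoh_montage`
#' @param lead lead id
#' @return character vector of adjacent lead ids
#' @export
montage_neighbors <- function(montage, lead) {
  if (!lead %in% montage$lead_ids) stop("lead '", lead, "' not in montage")
  montage$lead_ids[montage$adjacency[lead, ]]
}

#' Seed-based ROI: a center lead plus its six immediate neighbors
#'
#' Realizes the seed rule used for the motor-cortex ROI: the named center
#' lead together with the six leads immediately surrounding it in the
#' neighbor graph. When the center has more than six neighbors the six
#' nearest by Euclidean distance are taken, ties broken by label order.
#'
#' @param montage `fpcoh_montage`
#' @param center center lead id (e.g. `"C3"`)
#' @return character vector of exactly 7 lead ids, center first
#' @export
seed_roi_from_neighbors <- function(montage, center) {
  nb <- montage_neighbors(montage, center)
  if (length(nb) < 6L)
    stop("lead '", center, "' has only ", length(nb),
         " neighbors; 6 are required for the seed ROI")
  if (length(nb) > 6L) {
    ctr <- montage$positions[center, ]
    dd <- sqrt(rowSums((montage$positions[nb, , drop = FALSE] -
                          matrix(ctr, length(nb), ncol(montage$positions),
                                 byrow = TRUE))^2))
    nb <- nb[order(dd, nb)][1:6]
  }
  c(center, sort(nb))
}

k_nearest_leads <- function(montage, point, k, exclude = character()) {
  cand <- setdiff(montage$lead_ids, exclude)
  p <- montage$positions[cand, 1:2, drop = FALSE]
  dd <- sqrt((p[, 1] - point[1])^2 + (p[, 2] - point[2])^2)
  cand[order(dd, cand)][seq_len(k)]
}

new_roi_set <- function(rois, primary_pair, control_pairs, montage) {
  if (!all(lengths(rois) > 0))
    stop("empty ROI: ", paste(names(rois)[lengths(rois) == 0], collapse = ", "))
  for (nm in names(rois)) {
    leads <- rois[[nm]]
    if (anyDuplicated(leads))
      stop("ROI '", nm, "' lists a lead twice: ",
           paste(unique(leads[duplicated(leads)]), collapse = ", "))
    bad <- setdiff(leads, montage$lead_ids)
    if (length(bad))
      stop("ROI '", nm, "' names unknown leads: ", paste(bad, collapse = ", "))
  }
  pairs <- c(list(primary_pair), control_pairs)
  for (pr in pairs) {
    miss <- setdiff(pr, names(rois))
    if (length(miss))
      stop("ROI pair (", paste(pr, collapse = ","),
           ") references undefined ROI: ", paste(miss, collapse = ", "))
  }
  structure(list(rois = rois, primary_pair = primary_pair,
                 control_pairs = control_pairs),
            class = "fpcoh_roiset")
}

#' Load and validate a ROI configuration from JSON
#'
#' The JSON file maps ROI names to lead-id lists and names the primary and
#' control ROI pairs:
#' `{"rois": {"iM1": [...], ...}, "primary_pair": ["iM1","iPAR"],
#'   "control_pairs": [["iM1","cPAR"], ...]}`.
#' Every listed lead must exist in the montage; ROIs must be non-empty and
#' free of internal duplicates (the same lead may appear in several ROIs).
#'
#' @param path JSON config path
#' @param montage `fpcoh_montage` the leads are validated against
#' @return object of class `fpcoh_roiset`
#' @export
load_roi_config <- function(path, montage) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$rois)) stop("ROI config has no 'rois' entry")
  rois <- lapply(cfg$rois, as.character)
  primary <- if (is.null(cfg$primary_pair)) c("iM1", "iPAR")
             else as.character(cfg$primary_pair)
  ctrl <- list()
  if (!is.null(cfg$control_pairs)) {
    cp <- cfg$control_pairs
    ctrl <- if (is.matrix(cp)) lapply(seq_len(nrow(cp)), function(i) cp[i, ])
            else lapply(cp, as.character)
  }
  new_roi_set(rois, primary, ctrl, montage)
}

#' Write a ROI set to JSON
#' @param rois `fpcoh_roiset`
#' @param path output path
#' @export
write_roi_config <- function(rois, path) {
  jsonlite::write_json(list(rois = rois$rois,
                            primary_pair = rois$primary_pair,
                            control_pairs = rois$control_pairs),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Default ROI set for a synthetic hexagonal montage
#'
#' Builds the eight named ROIs of the analysis on a synthetic grid whose
#' center lead is the ipsilesional motor seed. Coordinates treat +y as
#' anterior and -x as the ipsilesional lateral direction; the midline is
#' placed at `x = 1.7` grid units so that contralesional ROIs sit mirrored
#' across it. The motor seed ROI uses the seed rule (center + 6 neighbors,
#' 7 leads); the lateral parietal ROI takes the 21 leads nearest a posterior
#' lateral centroid, excluding motor-seed leads; the remaining ROIs are the
#' leads nearest their nominal centroids. These lead sets are configuration,
#' not vendor geometry.
#'
#' @param montage `fpcoh_montage` with at least 5 rings (61 leads)
#' @param seed center lead id (default `"C3"`)
#' @return `fpcoh_roiset` with ROIs iM1, iPAR, cM1, cPAR, iPMd, iPf,
#'   iMedPr, iV1; primary pair iM1-iPAR; six control pairs
#' @export
default_roi_set <- function(montage, seed = "C3") {
  if (length(montage$lead_ids) < 61)
    stop("default ROI set needs a montage with >= 61 leads (5 rings)")
  iM1 <- seed_roi_from_neighbors(montage, seed)
  iPAR <- k_nearest_leads(montage, c(-1.2, -2.2), 21, exclude = iM1)
  # control ROIs stay clear of the primary pair's leads so that control
  # circuits measure genuinely different cortex
  used <- c(iM1, iPAR)
  rois <- list(
    iM1    = iM1,
    iPAR   = iPAR,
    cM1    = k_nearest_leads(montage, c(3.4, 0), 7, exclude = used),
    cPAR   = k_nearest_leads(montage, c(3.4, -2.2), 21, exclude = used),
    iPMd   = k_nearest_leads(montage, c(-0.6, 1.4), 7, exclude = used),
    iPf    = k_nearest_leads(montage, c(-1.4, 3.0), 7, exclude = used),
    iMedPr = k_nearest_leads(montage, c(1.0, -2.6), 7, exclude = used),
    iV1    = k_nearest_leads(montage, c(1.7, -3.6), 7, exclude = used))
  ctrl <- lapply(c("cPAR", "cM1", "iPMd", "iPf", "iMedPr", "iV1"),
                 function(r) c("iM1", r))
  new_roi_set(rois, c("iM1", "iPAR"), ctrl, montage)
}

#' @export
print.fpcoh_montage <- function(x, ...) {
  cat("fpcoh montage:", length(x$lead_ids), "leads,",
      sum(x$adjacency) / 2, "neighbor edges\n")
  invisible(x)
}

#' @export
print.fpcoh_roiset <- function(x, ...) {
  cat("fpcoh ROI set:",
      paste(sprintf("%s(%d)", names(x$rois), lengths(x$rois)), collapse = " "),
      "\n  primary:", paste(x$primary_pair, collapse = "-"), "\n")
  invisible(x)
}
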