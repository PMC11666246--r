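#' Link label masks across time-lapse frames into lineages
#'
#' Each mask at frame f+1 is assigned to the frame-f mask with which it shares
#' the maximum pixel overlap. Two masks linked to the same parent mask are a
#' cell division event: both children receive fresh cell ids and `parent_id`
#' set to the parent's cell id, provided each child's overlap exceeds
#' `min_child_overlap` of its own area (suppresses spurious splits). A mask
#' with no overlap starts a new lineage.
#'
#' @param masks list of integer label matrices (same dimensions, frames in
#'   order). Label 0 is background.
#' @param min_child_overlap minimum overlap fraction (of child area) for a
#'   division child to be linked rather than treated as a new cell.
#' @return data.frame: frame, label, cell_id, parent_id (NA if none), area_px.
#' @export
link_masks <- function(masks, min_child_overlap = 0.2) {
  stopifnot(length(masks) >= 1)
  dims <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), dims), logical(1))))
    stop("all masks must share dimensions")

  next_id <- 0L
  new_id <- function() { next_id <<- next_id + 1L; next_id }
  out <- list()

  labs <- setdiff(unique(as.vector(masks[[1]])), 0)
  id_of <- stats::setNames(vapply(labs, function(l) new_id(), integer(1)),
                           as.character(labs))
  area <- vapply(labs, function(l) sum(masks[[1]] == l), numeric(1))
  out[[1]] <- data.frame(frame = 1L, label = labs, cell_id = unname(id_of),
                         parent_id = NA_integer_, area_px = area)

  for (f in seq_along(masks)[-1]) {
    prev <- masks[[f - 1]]; cur <- masks[[f]]
    labs <- setdiff(unique(as.vector(cur)), 0)
    if (length(labs) == 0) { id_of <- integer(0); next }
    # overlap matrix: rows = current labels, cols = previous labels
    both <- prev > 0 & cur > 0
    ov <- if (any(both)) table(cur = cur[both], prev = prev[both]) else NULL
    assigned_parent <- rep(NA_character_, length(labs))
    names(assigned_parent) <- as.character(labs)
    best_ov <- stats::setNames(numeric(length(labs)), as.character(labs))
    for (l in as.character(labs)) {
      if (!is.null(ov) && l %in% rownames(ov)) {
        row <- ov[l, , drop = TRUE]
        if (max(row) > 0) {
          assigned_parent[l] <- colnames(ov)[which.max(row)]
          best_ov[l] <- max(row)
        }
      }
    }
    cur_area <- vapply(labs, function(l) sum(cur == l), numeric(1))
    names(cur_area) <- as.character(labs)
    new_ids <- integer(length(labs)); names(new_ids) <- as.character(labs)
    parent_ids <- rep(NA_integer_, length(labs)); names(parent_ids) <- as.character(labs)
    by_parent <- split(names(assigned_parent), assigned_parent)
    for (l in names(assigned_parent)[is.na(assigned_parent)]) new_ids[l] <- new_id()
    for (p in names(by_parent)) {
      kids <- by_parent[[p]]
      pid <- id_of[[p]]
      if (length(kids) == 1) {
        new_ids[kids] <- pid                       # continuation
      } else {
        ok <- best_ov[kids] / cur_area[kids] >= min_child_overlap
        for (kd in kids[ok]) { new_ids[kd] <- new_id(); parent_ids[kd] <- pid }
        for (kd in kids[!ok]) new_ids[kd] <- new_id()
      }
    }
    id_of <- new_ids
    out[[f]] <- data.frame(frame = f, label = as.integer(names(new_ids)),
                           cell_id = unname(new_ids),
                           parent_id = unname(parent_ids),
                           area_px = unname(cur_area))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Absolute and relative growth rates from a single-cell area series
#'
#' The area series is smoothed by a centered sliding average of `window`
#' points (edges truncated, no padding). The absolute growth rate is the
#' difference of the smoothed area between consecutive frames divided by the
#' sampling interval; the relative growth rate is the absolute rate divided
#' by the smoothed area. The output has `length(t) - window` rows: `window - 1`
#' points lost to smoothing, one more to differencing.
#'
#' @param t time points, min (strictly increasing, uniform spacing).
#' @param area cell area per time point, um^2 (> 0).
#' @param window sliding-average window, points. Default 5.
#' @param method "forward" (default) differences smoothed areas between
#'   consecutive frames; "central" uses the symmetric difference.
#' @return data.frame: t_min, area_smooth_um2, dadt_um2_min, rel_rate_per_min.
#'   `rel_rate * area_smooth == dadt` at every row.
#' @export
growth_rates <- function(t, area, window = 5, method = c("forward", "central")) {
  method <- match.arg(method)
  stopifnot(length(t) == length(area))
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  if (any(area <= 0)) stop("area must be > 0")
  if (length(t) < window + 1) stop("need at least window + 1 time points")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) stop("sampling must be uniform")
  dt <- dt[1]

  a_s <- stats::filter(area, rep(1 / window, window), sides = 2)
  keep <- !is.na(a_s)
  a_s <- as.numeric(a_s[keep]); ts <- t[keep]
  if (method == "forward") {
    dadt <- diff(a_s) / dt
    i <- seq_len(length(a_s) - 1)
  } else {
    n <- length(a_s)
    dadt <- (a_s[3:n] - a_s[1:(n - 2)]) / (2 * dt)
    i <- 2:(n - 1)
  }
  data.frame(t_min = ts[i], area_smooth_um2 = a_s[i], dadt_um2_min = dadt,
             rel_rate_per_min = dadt / a_s[i])
}

#' Truncate a growth series at its maximum absolute growth rate
#'
#' Filamenting cells eventually reach sizes too large to support growth; the
#' series is cut at the time point of maximum absolute growth rate
#' (inclusive) and later points are dropped.
#'
#' @param gs data.frame from [growth_rates()] (column `dadt_um2_min`).
#' @param rule "max" (default) cuts at the maximum; "fraction_of_max" cuts at
#'   the first point after the maximum where dA/dt drops below
#'   `frac` of the maximum.
#' @param frac fraction for `rule = "fraction_of_max"`.
#' @return the truncated data.frame.
#' @export
truncate_filament <- function(gs, rule = c("max", "fraction_of_max"), frac = 0.9) {
  rule <- match.arg(rule)
  if (nrow(gs) == 0) stop("empty growth series")
  j <- which.max(gs$dadt_um2_min)
  if (rule == "fraction_of_max" && j < nrow(gs)) {
    later <- which(gs$dadt_um2_min < frac * gs$dadt_um2_min[j])
    later <- later[later > j]
    if (length(later)) j <- min(later) - 1
    else j <- nrow(gs)
  }
  gs[seq_len(j), , drop = FALSE]
}

#' Convert projected cell area to volume (rod model)
#'
#' Models the cell as a cylinder with hemispherical caps whose 2D projection
#' matches the measured area at the measured width: the projection is a
#' rectangle of length L plus a disk of diameter w, so
#' `L = (A - pi w^2 / 4) / w` and `V = pi w^2 L / 4 + pi w^3 / 6`. A sphere
#' (L = 0) is the degenerate case.
#'
#' @param area projected area, um^2 (vectorized).
#' @param width cell width, um.
#' @return volume, um^3.
#' @export
area_to_volume <- function(area, width) {
  disk <- pi * width^2 / 4
  if (any(area < disk - 1e-12))
    stop("area smaller than the projection of a sphere of the given width")
  L <- pmax(0, (area - disk) / width)
  pi * width^2 * L / 4 + pi * width^3 / 6
}

#' Apparent relative growth rate under an additive segmentation bias
#'
#' For truly exponential growth `dA/dt = k A`, a constant segmentation offset
#' `eps` in the measured area A' = A + eps yields an apparent relative rate
#' `k A / (A + eps)`: increasing with A for eps > 0 (apparent super-exponential
#' growth) and decreasing for eps < 0.
#'
#' @param k true relative growth rate, 1/min.
#' @param epsilon additive offsets, um^2 (vector allowed).
#' @param areas true cell areas, um^2.
#' @return data.frame: epsilon_um2, area_um2 (true), measured_area_um2,
#'   apparent_rel_rate_per_min.
#' @export
segmentation_bias <- function(k, epsilon, areas) {
  grid <- expand.grid(epsilon_um2 = epsilon, area_um2 = areas)
  if (any(grid$area_um2 + grid$epsilon_um2 <= 0))
    stop("measured area A + epsilon must be positive")
  grid$measured_area_um2 <- grid$area_um2 + grid$epsilon_um2
  grid$apparent_rel_rate_per_min <- k * grid$area_um2 / grid$measured_area_um2
  grid
}
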