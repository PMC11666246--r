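#' Link single-molecule localizations into trajectories
#'
#' Localizations are linked within each cell: a position is appended to an
#' existing trajectory if it appears within `radius` of the trajectory head in
#' the next frame, with a single-frame disappearance (blinking) bridged when
#' `max_gap = 1`. Ambiguity terminates involvement: if two or more
#' localizations fall within the tracking radius of a head, those
#' localizations are omitted from the analysis and the trajectory ends; a
#' localization reachable from two heads is likewise omitted.
#'
#' @param locs data.frame: frame, x_um, y_um, cell_id.
#' @param radius tracking radius, um. Default 0.8.
#' @param max_gap maximum bridged frame disappearance. Default 1.
#' @return data.frame: track_id, frame, x_um, y_um, cell_id.
#' @export
link_localizations <- function(locs, radius = 0.8, max_gap = 1) {
  stopifnot(all(c("frame", "x_um", "y_um", "cell_id") %in% names(locs)))
  next_tid <- 0L
  res <- list()
  for (cl in split(locs, locs$cell_id)) {
    cl <- cl[order(cl$frame), ]
    heads <- data.frame(track_id = integer(0), frame = integer(0),
                        x = numeric(0), y = numeric(0))
    rows <- vector("list", nrow(cl) + 64)
    nrow_used <- 0
    add_row <- function(tid, fr, x, y, cid) {
      nrow_used <<- nrow_used + 1
      rows[[nrow_used]] <<- data.frame(track_id = tid, frame = fr,
                                       x_um = x, y_um = y, cell_id = cid)
    }
    for (f in sort(unique(cl$frame))) {
      pts <- cl[cl$frame == f, ]
      heads <- heads[heads$frame >= f - 1 - max_gap, , drop = FALSE]
      np <- nrow(pts); nh <- nrow(heads)
      if (nh > 0 && np > 0) {
        d <- sqrt(outer(heads$x, pts$x_um, "-")^2 + outer(heads$y, pts$y_um, "-")^2)
        within <- d <= radius
        cand_per_head <- rowSums(within)
        cand_per_pt <- colSums(within)
        pt_linked <- rep(FALSE, np); pt_omit <- rep(FALSE, np)
        head_drop <- rep(FALSE, nh)
        # ambiguous heads: >= 2 candidate localizations -> those locs omitted
        for (h in which(cand_per_head >= 2)) {
          pt_omit[within[h, ]] <- TRUE
          head_drop[h] <- TRUE
        }
        # ambiguous localizations: reachable from >= 2 heads -> omitted
        pt_omit[cand_per_pt >= 2] <- TRUE
        for (h in which(cand_per_head == 1 & !head_drop)) {
          p <- which(within[h, ])
          if (!pt_omit[p] && !pt_linked[p]) {
            add_row(heads$track_id[h], pts$frame[p], pts$x_um[p], pts$y_um[p],
                    pts$cell_id[p])
            heads$frame[h] <- pts$frame[p]
            heads$x[h] <- pts$x_um[p]; heads$y[h] <- pts$y_um[p]
            pt_linked[p] <- TRUE
          } else head_drop[h] <- TRUE
        }
        heads <- heads[!head_drop, , drop = FALSE]
        new_pts <- which(!pt_linked & !pt_omit)
      } else new_pts <- seq_len(np)
      for (p in new_pts) {
        next_tid <- next_tid + 1L
        add_row(next_tid, pts$frame[p], pts$x_um[p], pts$y_um[p], pts$cell_id[p])
        heads <- rbind(heads, data.frame(track_id = next_tid, frame = pts$frame[p],
                                         x = pts$x_um[p], y = pts$y_um[p]))
      }
    }
    res[[length(res) + 1]] <- do.call(rbind, rows[seq_len(nrow_used)])
  }
  out <- do.call(rbind, res)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Apparent diffusion coefficients from trajectories
#'
#' Computes, per track, the apparent diffusion coefficient from the stepwise
#' mean-squared displacement:
#' `D_a = 1/(4 n dt) * sum_i [ (x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2 ]`
#' over the n consecutive-frame displacements of the trajectory. Tracks with
#' fewer than `min_displacements` displacements are omitted (higher
#' uncertainty in D_a), not an error. Displacements spanning a bridged
#' (blinked) frame are excluded by default; `gap_policy = "half"` includes
#' them with the doubled time interval.
#'
#' @param tracks data.frame: track_id, frame, x_um, y_um, cell_id.
#' @param frame_time camera frame time, s. Default 0.0107.
#' @param min_displacements minimum displacement count to retain a record.
#'   Default 9.
#' @param gap_policy "exclude" (default) or "half".
#' @return data.frame: track_id, cell_id, da_um2s, n_disp.
#' @export
apparent_diffusion <- function(tracks, frame_time = 0.0107,
                               min_displacements = 9,
                               gap_policy = c("exclude", "half")) {
  gap_policy <- match.arg(gap_policy)
  if (frame_time <= 0) stop("frame_time must be > 0")
  per <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (any(diff(tr$frame) <= 0)) stop("frames must be strictly increasing")
    df <- diff(tr$frame)
    sq <- diff(tr$x_um)^2 + diff(tr$y_um)^2
    if (gap_policy == "exclude") {
      use <- df == 1
      n <- sum(use)
      da <- if (n > 0) sum(sq[use]) / (4 * n * frame_time) else NA_real_
    } else {
      use <- df <= 2
      n <- sum(use)
      da <- if (n > 0) sum(sq[use] / (4 * df[use] * frame_time)) / n else NA_real_
    }
    data.frame(track_id = tr$track_id[1], cell_id = tr$cell_id[1],
               da_um2s = da, n_disp = n)
  })
  out <- do.call(rbind, per)
  out <- out[!is.na(out$da_um2s) & out$n_disp >= min_displacements, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a Gaussian mixture to log10 apparent diffusion coefficients
#'
#' Fits a k-component (default 3: engaged/"active", diffusing, free) Gaussian
#' mixture with unequal variances to log10-transformed D_a values by
#' maximum-likelihood EM (`mclust`'s EM engine) with seeded multistart:
#' one k-means-based start plus `restarts - 1` random starts, keeping the
#' best log-likelihood. Zero or sub-floor D_a values are floored at `floor`
#' (below all physical states) before the log transform. Components are
#' reported slowest-first.
#'
#' @param da apparent diffusion coefficients, um^2/s, or a data.frame from
#'   [apparent_diffusion()].
#' @param k number of states. Default 3.
#' @param floor lower bound applied to D_a before log10. Default 1e-5.
#' @param restarts EM starts (first is k-means-based). Default 10.
#' @param tol EM log-likelihood tolerance. Default 1e-6.
#' @param seed integer seed for the restarts.
#' @return object of class `gmm_fit`: list(weights, means, sds, k, loglik,
#'   floor) with components sorted by mean (log10 um^2/s).
#' @export
fit_gmm_log_da <- function(da, k = 3, floor = 1e-5, restarts = 10,
                           tol = 1e-6, seed = 1) {
  if (is.data.frame(da)) da <- da$da_um2s
  if (length(da) < 10 * k) stop("need at least 10 * k records")
  x <- log10(pmax(da, floor))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(restarts)) {
    par0 <- try({
      if (s == 1) {
        km <- stats::kmeans(x, centers = k, nstart = 5)
        mu <- as.numeric(km$centers)
        list(pro = as.numeric(table(km$cluster)) / length(x), mean = mu,
             variance = list(modelName = "V", d = 1, G = k,
                             sigmasq = pmax(tapply(x, km$cluster, stats::var),
                                            1e-6)))
      } else {
        list(pro = rep(1 / k, k), mean = sample(x, k),
             variance = list(modelName = "V", d = 1, G = k,
                             sigmasq = rep(stats::var(x) / k, k)))
      }
    }, silent = TRUE)
    if (inherits(par0, "try-error")) next
    fit <- try(mclust::emV(x, parameters = par0,
                           control = mclust::emControl(tol = c(tol, tol))),
               silent = TRUE)
    if (inherits(fit, "try-error") || is.null(fit$loglik) ||
        !is.finite(fit$loglik)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best))
    stop("EM failed to converge in all restarts; inspect the D_a distribution")
  ord <- order(best$parameters$mean)
  out <- list(weights = unname(best$parameters$pro[ord]),
              means = unname(best$parameters$mean[ord]),
              sds = unname(sqrt(best$parameters$variance$sigmasq[ord])),
              k = k, loglik = best$loglik, floor = floor)
  class(out) <- "gmm_fit"
  out
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture on log10(D_a), %d states (slowest first)\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  state %d: weight %.3f, mean %.3f, sd %.3f (D_a ~ %.3g um^2/s)\n",
                i, x$weights[i], x$means[i], x$sds[i], 10^x$means[i]))
  invisible(x)
}

#' Posterior state probabilities and assignments under a fitted mixture
#'
#' @param gmm a `gmm_fit`.
#' @param da D_a values, um^2/s.
#' @return data.frame with `state` (max-posterior, 1 = slowest) and one
#'   posterior column per state.
#' @export
classify_da <- function(gmm, da) {
  x <- log10(pmax(da, gmm$floor))
  dens <- vapply(seq_len(gmm$k), function(i)
    gmm$weights[i] * stats::dnorm(x, gmm$means[i], gmm$sds[i]),
    numeric(length(x)))
  dens <- matrix(dens, ncol = gmm$k)
  post <- dens / pmax(rowSums(dens), .Machine$double.xmin)
  out <- data.frame(state = max.col(post, ties.method = "first"))
  colnames(post) <- paste0("posterior_", seq_len(gmm$k))
  cbind(out, as.data.frame(post))
}

#' Per-cell active (slow-state) fractions
#'
#' Assigns each diffusion record its maximum-posterior mixture state and
#' computes, per cell, the fraction of records in the slowest ("active")
#' state. Cells with fewer than `min_tracks` records are dropped. With
#' `soft = TRUE` the mean posterior probability of the slowest state is used
#' instead of the hard assignment.
#'
#' @param records data.frame from [apparent_diffusion()] (cell_id, da_um2s).
#' @param gmm a `gmm_fit`.
#' @param min_tracks minimum records per retained cell. Default 50.
#' @param soft logical; soft (posterior-mean) fractions.
#' @return data.frame: cell_id, n_tracks, active_fraction.
#' @export
cell_active_fractions <- function(records, gmm, min_tracks = 50, soft = FALSE) {
  cls <- classify_da(gmm, records$da_um2s)
  val <- if (soft) cls$posterior_1 else as.numeric(cls$state == 1)
  agg <- stats::aggregate(val, list(cell_id = records$cell_id),
                          function(v) c(n = length(v), f = mean(v)))
  out <- data.frame(cell_id = agg$cell_id, n_tracks = agg$x[, "n"],
                    active_fraction = agg$x[, "f"])
  out[out$n_tracks >= min_tracks, , drop = FALSE]
}

#' Total active molecules per cell, binned by cell area
#'
#' The total quantity of active molecules per cell is the measured total
#' fluorescence intensity multiplied by the measured active fraction; the
#' per-cell values are binned by cell area with a percentile-bootstrap CI of
#' the per-bin mean (see [bootstrap_binned_mean()]).
#'
#' @param stats data.frame: cell_id, area_um2, active_fraction,
#'   total_fluorescence.
#' @param bin_edges area bin edges, um^2.
#' @param n_boot bootstrap replicates. Default 1000.
#' @param seed integer seed for the bootstrap.
#' @return list with `per_cell` (input plus `total_active`) and `binned`
#'   (data.frame from [bootstrap_binned_mean()]).
#' @export
total_active_curve <- function(stats, bin_edges, n_boot = 1000, seed = NULL) {
  needed <- c("area_um2", "active_fraction", "total_fluorescence")
  stopifnot(all(needed %in% names(stats)))
  stats$total_active <- stats$total_fluorescence * stats$active_fraction
  binned <- bootstrap_binned_mean(stats$total_active, stats$area_um2,
                                  bin_edges, n_boot = n_boot, seed = seed)
  list(per_cell = stats, binned = binned)
}
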