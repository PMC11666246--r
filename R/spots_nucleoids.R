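#' Detect fluorescent spots by band-pass filtering and 2D Gaussian fitting
#'
#' Candidate spots are local maxima of a difference-of-Gaussians band-pass
#' filtered image (`sigma_low` and `sigma_high`, px). Each candidate is fitted
#' in a square window with an isotropic 2D Gaussian (amplitude, center, sigma,
#' offset). A quality score `intensity * quality_fit / sigma_fit` is computed,
#' where `quality_fit = 1 - RSS/TSS` of the Gaussian fit clipped to (0, 1],
#' and spots with score below `score_threshold` are discarded. Candidates
#' whose fit diverges are dropped.
#'
#' @param image numeric matrix.
#' @param cell_masks optional integer label matrix; candidates outside cells
#'   are ignored and each spot carries its cell id.
#' @param score_threshold minimum spot score, a.u. Default 0.
#' @param sigma_low,sigma_high band-pass (difference-of-Gaussians) SDs, px.
#' @param window half-width of the fitting window, px. Default 5.
#' @param min_peak minimum band-pass response for a candidate, in units of
#'   the band-pass image SD. Default 3.
#' @return data.frame: x_px, y_px (sub-pixel, matrix row/col coordinates),
#'   intensity (fitted amplitude), sigma_px, quality_fit, score, cell_id.
#' @export
detect_spots <- function(image, cell_masks = NULL, score_threshold = 0,
                         sigma_low = 1, sigma_high = 5, window = 5,
                         min_peak = 3) {
  if (score_threshold < 0) stop("score_threshold must be >= 0")
  stopifnot(length(dim(image)) == 2)
  bp <- as.matrix(EBImage::gblur(image, sigma = sigma_low)) -
    as.matrix(EBImage::gblur(image, sigma = sigma_high))
  thr <- min_peak * stats::sd(as.vector(bp))
  nr <- nrow(image); nc <- ncol(image)
  cand <- which(bp > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr & cand[, 2] > 1 & cand[, 2] < nc, ,
               drop = FALSE]
  if (nrow(cand) > 0) {
    is_max <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      bp[r, c] >= max(bp[(r - 1):(r + 1), (c - 1):(c + 1)])
    }, logical(1))
    cand <- cand[is_max, , drop = FALSE]
  }
  out <- list()
  for (i in seq_len(nrow(cand))) {
    r0 <- unname(cand[i, 1]); c0 <- unname(cand[i, 2])
    cid <- if (!is.null(cell_masks)) cell_masks[r0, c0] else NA_integer_
    if (!is.null(cell_masks) && cid == 0) next
    rr <- max(1, r0 - window):min(nr, r0 + window)
    cc <- max(1, c0 - window):min(nc, c0 + window)
    z <- image[rr, cc]
    dat <- data.frame(r = rep(rr, times = length(cc)),
                      c = rep(cc, each = length(rr)), z = as.vector(z))
    fit <- try(minpack.lm::nlsLM(
      z ~ off + amp * exp(-((r - x0)^2 + (c - y0)^2) / (2 * s^2)),
      data = dat,
      start = list(off = min(dat$z), amp = image[r0, c0] - min(dat$z),
                   x0 = r0, y0 = c0, s = 1.5),
      lower = c(off = -Inf, amp = 0, x0 = min(rr), y0 = min(cc), s = 0.3),
      upper = c(off = Inf, amp = Inf, x0 = max(rr), y0 = max(cc),
                s = 2 * window),
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cf <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
    tss <- sum((dat$z - mean(dat$z))^2)
    quality <- if (tss > 0) max(min(1 - rss / tss, 1), .Machine$double.eps) else 1
    score <- cf["amp"] * quality / cf["s"]
    out[[length(out) + 1]] <- data.frame(
      x_px = unname(cf["x0"]), y_px = unname(cf["y0"]),
      intensity = unname(cf["amp"]), sigma_px = unname(cf["s"]),
      quality_fit = quality, score = unname(score), cell_id = cid)
  }
  if (length(out) == 0)
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), sigma_px = numeric(0),
                      quality_fit = numeric(0), score = numeric(0),
                      cell_id = integer(0)))
  res <- do.call(rbind, out)
  res <- res[res$score >= score_threshold, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# two-threshold (three-class) Otsu on a numeric vector; returns the two
# thresholds maximizing between-class variance on a binned histogram
otsu_multilevel <- function(x, n_bins = 64) {
  rng <- range(x)
  if (diff(rng) == 0) return(c(rng[1], rng[1]))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  p <- h / sum(h)
  best <- -Inf; thr <- c(1, 2)
  cw <- cumsum(p); cm <- cumsum(p * mids)
  total_mean <- cm[n_bins]
  for (i in 1:(n_bins - 2)) for (j in (i + 1):(n_bins - 1)) {
    w1 <- cw[i]; w2 <- cw[j] - cw[i]; w3 <- 1 - cw[j]
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) next
    m1 <- cm[i] / w1; m2 <- (cm[j] - cm[i]) / w2; m3 <- (total_mean - cm[j]) / w3
    v <- w1 * (m1 - total_mean)^2 + w2 * (m2 - total_mean)^2 +
      w3 * (m3 - total_mean)^2
    if (v > best) { best <- v; thr <- c(i, j) }
  }
  c(br[thr[1] + 1], br[thr[2] + 1])
}

#' Count nucleoids per cell and classify ploidy
#'
#' Within each cell mask, DNA-signal foreground is found either by
#' two-threshold Otsu on the within-cell intensities (foreground = highest
#' class; `method = "otsu"`) or by the snapshot variant combining a Laplacian
#' of Gaussian filter, an adaptive (local-mean) filter and a hard threshold
#' (`method = "snapshot"`). Connected components within the cell are filtered
#' by area, and the surviving count classifies ploidy: 1 nucleoid = "1N",
#' 2 or more = "multiN", 0 = "ambiguous".
#'
#' @param dna_image numeric matrix of DNA signal.
#' @param cell_masks integer label matrix, aligned with `dna_image`.
#' @param min_area,max_area nucleoid area bounds, px.
#' @param method "otsu" (default) or "snapshot".
#' @param log_sigma LoG scale for the snapshot method, px.
#' @param hard_quantile hard-threshold quantile (within cell) for the
#'   snapshot method.
#' @return list with `counts` (data.frame: cell_id, n_nucleoids, class) and
#'   `labels` (integer matrix of nucleoid component labels).
#' @export
count_nucleoids <- function(dna_image, cell_masks, min_area = 4,
                            max_area = Inf, method = c("otsu", "snapshot"),
                            log_sigma = 2, hard_quantile = 0.5) {
  method <- match.arg(method)
  if (min_area >= max_area) stop("min_area must be < max_area")
  stopifnot(identical(dim(dna_image), dim(cell_masks)))
  lab_out <- matrix(0L, nrow(dna_image), ncol(dna_image))
  next_lab <- 0L
  rows <- list()
  if (method == "snapshot") {
    sm <- as.matrix(EBImage::gblur(dna_image, sigma = log_sigma))
    # LoG response approximated by the (negated) discrete Laplacian of the blur
    lap <- matrix(0, nrow(sm), ncol(sm))
    n <- nrow(sm); m <- ncol(sm)
    lap[2:(n - 1), 2:(m - 1)] <-
      4 * sm[2:(n - 1), 2:(m - 1)] - sm[1:(n - 2), 2:(m - 1)] -
      sm[3:n, 2:(m - 1)] - sm[2:(n - 1), 1:(m - 2)] - sm[2:(n - 1), 3:m]
    local_mean <- as.matrix(EBImage::gblur(dna_image, sigma = 4 * log_sigma))
  }
  for (cid in setdiff(sort(unique(as.vector(cell_masks))), 0)) {
    sel <- cell_masks == cid
    if (!any(sel)) {
      rows[[length(rows) + 1]] <- data.frame(cell_id = cid, n_nucleoids = 0L,
                                             class = "ambiguous")
      next
    }
    vals <- dna_image[sel]
    fg <- matrix(FALSE, nrow(dna_image), ncol(dna_image))
    if (method == "otsu") {
      thr <- otsu_multilevel(vals)
      fg[sel] <- dna_image[sel] > thr[2]
    } else {
      hard <- stats::quantile(vals, hard_quantile)
      fg[sel] <- lap[sel] > 0 & dna_image[sel] > local_mean[sel] &
        dna_image[sel] > hard
    }
    comp <- EBImage::bwlabel(fg)
    comp <- as.matrix(comp)
    sizes <- tabulate(comp[comp > 0])
    keep <- which(sizes >= min_area & sizes <= max_area)
    cnt <- length(keep)
    for (k in keep) {
      next_lab <- next_lab + 1L
      lab_out[comp == k] <- next_lab
    }
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = cid, n_nucleoids = cnt,
      class = if (cnt == 1) "1N" else if (cnt >= 2) "multiN" else "ambiguous")
  }
  list(counts = do.call(rbind, rows), labels = lab_out)
}

#' Background-subtracted total fluorescence per cell
#'
#' Subtracts the median intensity outside all cell masks from each pixel of a
#' cell and sums the result; totals can be negative for empty cells and are
#' reported as-is.
#'
#' @param image numeric matrix.
#' @param cell_masks integer label matrix (0 = background).
#' @return data.frame: cell_id, total_fluorescence, area_px.
#' @export
total_cell_fluorescence <- function(image, cell_masks) {
  stopifnot(identical(dim(image), dim(cell_masks)))
  bg_px <- image[cell_masks == 0]
  if (length(bg_px) == 0) stop("masks cover the entire image; no background")
  bg <- stats::median(bg_px)
  ids <- setdiff(sort(unique(as.vector(cell_masks))), 0)
  do.call(rbind, lapply(ids, function(cid) {
    v <- image[cell_masks == cid]
    data.frame(cell_id = cid, total_fluorescence = sum(v - bg),
               area_px = length(v))
  }))
}
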