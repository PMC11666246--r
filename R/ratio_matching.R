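#' Match the cell-area distributions of two populations
#'
#' Within each shared area bin, the larger population is randomly subsampled
#' without replacement to the size of the smaller one, so both populations
#' retain exactly equal per-bin counts. Bins where either population has
#' fewer than `min_per_bin` cells (pooled across replicates) are dropped.
#'
#' @param pop data.frame: area_um2, signal, replicate, population (two
#'   levels).
#' @param bin_edges shared area bin edges, um^2.
#' @param min_per_bin minimum cells per population per retained bin.
#'   Default 50.
#' @param seed integer seed.
#' @return data.frame of retained rows (same columns, plus `bin`).
#' @export
match_distributions <- function(pop, bin_edges, min_per_bin = 50, seed = NULL) {
  pops <- unique(pop$population)
  if (length(pops) != 2) stop("exactly two populations required")
  if (!is.null(seed)) set.seed(seed)
  pop$bin <- cut(pop$area_um2, bin_edges, labels = FALSE)
  pop <- pop[!is.na(pop$bin), , drop = FALSE]
  keep <- list()
  for (b in sort(unique(pop$bin))) {
    a <- pop[pop$bin == b & pop$population == pops[1], , drop = FALSE]
    b2 <- pop[pop$bin == b & pop$population == pops[2], , drop = FALSE]
    if (nrow(a) < min_per_bin || nrow(b2) < min_per_bin) next
    n <- min(nrow(a), nrow(b2))
    keep[[length(keep) + 1]] <- rbind(a[sample.int(nrow(a), n), , drop = FALSE],
                                      b2[sample.int(nrow(b2), n), , drop = FALSE])
  }
  if (length(keep) == 0) stop("no overlapping bins above min_per_bin")
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Bootstrapped per-bin concentration ratio between two populations
#'
#' For each biological replicate and area bin, repeated equal-n resampling
#' with replacement compares the two populations: the sample size is the
#' smaller of the two per-bin counts and the number of iterations is
#' 10 x |n_A - n_B| (floored at 1 when the counts are equal, where a single
#' resample already uses all cells). The per-iteration statistic is the ratio
#' of sample means (population A over population B); per replicate the mean
#' over iterations is kept, then aggregated across replicates. Bins with
#' fewer than `min_per_replicate` cells in either population within a
#' replicate are dropped for that replicate.
#'
#' @param pop data.frame: area_um2, signal, replicate, population.
#' @param bin_edges area bin edges, um^2. Default 1-um^2 bins over 2-10 um^2.
#' @param min_per_replicate minimum per-bin per-replicate cells. Default 10.
#' @param iter_factor multiplier on |n_A - n_B| for the iteration count.
#'   Default 10.
#' @param max_iter upper cap on iterations per replicate-bin (cost control).
#' @param statistic "mean_of_ratios" (default) averages per-iteration
#'   mean_A/mean_B ratios; "ratio_of_means" forms the ratio of the
#'   iteration-averaged means.
#' @param ref_population which population is the numerator; default the first
#'   level encountered.
#' @param seed integer seed.
#' @return data.frame of class `binned_ratio`: bin_center_um2, ratio,
#'   ratio_sd, n_a, n_b, n_replicates.
#' @export
ratio_vs_area <- function(pop, bin_edges = 2:10, min_per_replicate = 10,
                          iter_factor = 10, max_iter = 2000,
                          statistic = c("mean_of_ratios", "ratio_of_means"),
                          ref_population = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  pops <- unique(pop$population)
  if (length(pops) != 2) stop("exactly two populations required")
  if (is.null(ref_population)) ref_population <- pops[1]
  other <- setdiff(pops, ref_population)
  if (!is.null(seed)) set.seed(seed)
  pop$bin <- cut(pop$area_um2, bin_edges, labels = FALSE)
  pop <- pop[!is.na(pop$bin), , drop = FALSE]
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2

  rows <- list()
  for (b in sort(unique(pop$bin))) {
    per_rep <- c(); na_tot <- nb_tot <- 0L
    for (r in unique(pop$replicate)) {
      a <- pop$signal[pop$bin == b & pop$replicate == r &
                        pop$population == ref_population]
      bb <- pop$signal[pop$bin == b & pop$replicate == r &
                         pop$population == other]
      if (length(a) < min_per_replicate || length(bb) < min_per_replicate) next
      n <- min(length(a), length(bb))
      n_iter <- min(max_iter, max(1, iter_factor * abs(length(a) - length(bb))))
      ma <- mb <- numeric(n_iter)
      for (it in seq_len(n_iter)) {
        ma[it] <- mean(a[sample.int(length(a), n, replace = TRUE)])
        mb[it] <- mean(bb[sample.int(length(bb), n, replace = TRUE)])
      }
      ok <- mb != 0
      if (!any(ok)) next
      val <- if (statistic == "mean_of_ratios") mean(ma[ok] / mb[ok])
             else mean(ma[ok]) / mean(mb[ok])
      per_rep <- c(per_rep, val)
      na_tot <- na_tot + length(a); nb_tot <- nb_tot + length(bb)
    }
    if (length(per_rep) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      bin_center_um2 = centers[b], ratio = mean(per_rep),
      ratio_sd = if (length(per_rep) > 1) stats::sd(per_rep) else NA_real_,
      n_a = na_tot, n_b = nb_tot, n_replicates = length(per_rep))
  }
  if (length(rows) == 0) stop("no bins retained; check bin edges and counts")
  out <- do.call(rbind, rows)
  class(out) <- c("binned_ratio", class(out))
  out
}

#' Fit a single exponential decay to binned ratios
#'
#' Least-squares fit of `ratio(A) = a * exp(-b * A)` to the per-bin average
#' ratios, with R^2 reported.
#'
#' @param binned data.frame with columns bin_center_um2 and ratio (e.g. from
#'   [ratio_vs_area()]).
#' @return list of class `decay_fit`: a (amplitude), b (decay rate per um^2),
#'   r_squared, fitted (data.frame bin_center_um2, fitted_ratio).
#' @export
fit_exponential_decay <- function(binned) {
  if (nrow(binned) < 3) stop("need at least 3 bins")
  A <- binned$bin_center_um2; y <- binned$ratio
  # log-linear start values (valid: ratios > 0)
  st <- stats::lm(log(y) ~ A)
  fit <- minpack.lm::nlsLM(y ~ a * exp(-b * A),
                           start = list(a = exp(unname(stats::coef(st)[1])),
                                        b = -unname(stats::coef(st)[2])),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pred <- stats::predict(fit)
  rss <- sum((y - pred)^2); tss <- sum((y - mean(y))^2)
  out <- list(a = unname(stats::coef(fit)["a"]), b = unname(stats::coef(fit)["b"]),
              r_squared = if (tss > 0) 1 - rss / tss else 1,
              fitted = data.frame(bin_center_um2 = A, fitted_ratio = pred))
  class(out) <- "decay_fit"
  out
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("ratio(A) = %.4g * exp(-%.4g * A), R^2 = %.4f\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Percentile-bootstrap mean and 95% CI per area bin
#'
#' @param values per-cell values.
#' @param areas matching cell areas, um^2.
#' @param bin_edges area bin edges, um^2.
#' @param n_boot bootstrap replicates (>= 100). Default 1000.
#' @param seed integer seed.
#' @return data.frame: bin_center_um2, n, mean, ci_lo, ci_hi (2.5/97.5
#'   percentiles of the bootstrapped mean). Empty bins are absent.
#' @export
bootstrap_binned_mean <- function(values, areas, bin_edges, n_boot = 1000,
                                  seed = NULL) {
  stopifnot(length(values) == length(areas))
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  bin <- cut(areas, bin_edges, labels = FALSE)
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  rows <- list()
  for (b in sort(unique(bin[!is.na(bin)]))) {
    v <- values[!is.na(bin) & bin == b]
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(v[sample.int(length(v), replace = TRUE)]),
                 numeric(1))
    q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(bin_center_um2 = centers[b],
                                           n = length(v), mean = mean(v),
                                           ci_lo = q[1], ci_hi = q[2])
  }
  do.call(rbind, rows)
}
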