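#' Simulate single-molecule tracks from a multi-state diffusivity mixture
#'
#' Generates 2D Brownian trajectories inside a rod-shaped cell. Each track is
#' assigned one diffusive state drawn from `weights` and keeps it for its whole
#' life (no state switching). Per-axis step displacements are Gaussian with SD
#' `sqrt(2 * D * frame_time)` and are specularly reflected at the cell boundary
#' (approximated by the bounding rectangle of the rod projection). Localization
#' error is added independently per localization and per axis, which inflates
#' the apparent diffusion coefficient by `loc_error_sd^2 / frame_time`, as in
#' real single-particle tracking.
#'
#' @param n_tracks number of tracks to generate.
#' @param weights state probabilities; must sum to 1 (tolerance 1e-12).
#' @param d_um2s diffusion coefficient per state, um^2/s (non-negative).
#' @param loc_error_sd localization error SD per axis, um.
#' @param frame_time camera frame time, s. Default 0.0107 (10.7 ms).
#' @param track_length number of localizations per track; scalar or vector of
#'   length `n_tracks` (recycled by sampling with replacement otherwise).
#' @param cell_length,cell_width rod dimensions, um.
#' @param n_cells tracks are distributed round-robin over this many cell ids.
#' @param seed integer seed; all randomness in the call flows from it.
#'
#' @return list with `tracks` (data.frame: track_id, frame, x_um, y_um,
#'   cell_id) and `truth` (data.frame: track_id, state, d_true_um2s).
#' @export
sim_tracks <- function(n_tracks, weights, d_um2s, loc_error_sd = 0,
                       frame_time = 0.0107, track_length = 12,
                       cell_length = 3, cell_width = 1, n_cells = 1,
                       seed = NULL) {
  stopifnot(n_tracks >= 1, length(weights) == length(d_um2s))
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (any(d_um2s < 0)) stop("d_values must be >= 0")
  if (frame_time <= 0) stop("frame_time must be > 0")
  if (!is.null(seed)) set.seed(seed)

  n_states <- length(weights)
  state <- sample.int(n_states, n_tracks, replace = TRUE, prob = weights)
  len <- if (length(track_length) == 1) rep(track_length, n_tracks)
         else if (length(track_length) == n_tracks) track_length
         else sample(track_length, n_tracks, replace = TRUE)
  if (any(len < 2)) stop("track_length must be >= 2")

  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    d <- d_um2s[state[i]]
    step_sd <- sqrt(2 * d * frame_time)
    x <- numeric(len[i]); y <- numeric(len[i])
    x[1] <- stats::runif(1, 0, cell_length)
    y[1] <- stats::runif(1, 0, cell_width)
    if (len[i] > 1) {
      dx <- stats::rnorm(len[i] - 1, 0, step_sd)
      dy <- stats::rnorm(len[i] - 1, 0, step_sd)
      for (j in 2:len[i]) {
        x[j] <- .reflect(x[j - 1] + dx[j - 1], 0, cell_length)
        y[j] <- .reflect(y[j - 1] + dy[j - 1], 0, cell_width)
      }
    }
    ex <- if (loc_error_sd > 0) stats::rnorm(len[i], 0, loc_error_sd) else 0
    ey <- if (loc_error_sd > 0) stats::rnorm(len[i], 0, loc_error_sd) else 0
    out[[i]] <- data.frame(track_id = i, frame = seq_len(len[i]) - 1L,
                           x_um = x + ex, y_um = y + ey,
                           cell_id = ((i - 1L) %% n_cells) + 1L)
  }
  list(tracks = do.call(rbind, out),
       truth = data.frame(track_id = seq_len(n_tracks), state = state,
                          d_true_um2s = d_um2s[state]))
}

# specular reflection of a scalar into [lo, hi]
.reflect <- function(z, lo, hi) {
  w <- hi - lo
  z <- (z - lo) %% (2 * w)
  ifelse(z > w, 2 * w - z, z) + lo
}

#' Simulate single-cell area trajectories
#'
#' Area trajectories for one or more cells, sampled every `sample_interval`
#' minutes. `mode = "exponential"` gives `a0 * exp(k * t)`; `mode = "linear"`
#' gives `a0 + k * a0 * t`; `mode = "model_driven"` integrates the DNA-limited
#' expression model (see [simulate_model()]) under the `oneN` genome law and
#' uses its area path. The noiseless path is then multiplied by lognormal noise
#' (sdlog = `noise_sd`) and shifted by the additive segmentation offset
#' `area_bias`, in that order, so the bias survives averaging — the ingredient
#' of the apparent super-exponential growth artifact.
#'
#' @param n_cells number of cells.
#' @param mode one of "exponential", "linear", "model_driven".
#' @param k relative growth rate, 1/min; scalar or per-cell vector.
#' @param a0 initial area, um^2 (> 0); scalar or per-cell vector.
#' @param t_end,sample_interval trajectory span and sampling interval, min.
#' @param area_bias additive segmentation offset, um^2.
#' @param noise_sd sdlog of multiplicative lognormal measurement noise.
#' @param width cell width, um (constant during filamentation).
#' @param model_params,genome_law passed to [simulate_model()] when
#'   `mode = "model_driven"`.
#' @param seed integer seed.
#' @return data.frame: cell_id, t_min, area_um2, width_um.
#' @export
sim_growth <- function(n_cells = 1, mode = c("exponential", "linear", "model_driven"),
                       k = 0.01, a0 = 2, t_end = 100, sample_interval = 1,
                       area_bias = 0, noise_sd = 0, width = 1,
                       model_params = NULL, genome_law = "oneN", seed = NULL) {
  mode <- match.arg(mode)
  if (any(a0 <= 0)) stop("a0 must be > 0")
  if (sample_interval <= 0) stop("sample_interval must be > 0")
  if (!is.null(seed)) set.seed(seed)
  k <- rep_len(k, n_cells); a0 <- rep_len(a0, n_cells)
  t <- seq(0, t_end, by = sample_interval)

  if (mode == "model_driven") {
    if (is.null(model_params)) model_params <- model_params()
    traj <- simulate_model(model_params, genome_law = genome_law,
                           t_end = t_end, dt_out = sample_interval)
  }
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    a_true <- switch(mode,
      exponential = a0[i] * exp(k[i] * t),
      linear = a0[i] + k[i] * a0[i] * t,
      model_driven = traj$A / traj$A[1] * a0[i])
    noise <- if (noise_sd > 0) stats::rlnorm(length(t), 0, noise_sd) else 1
    out[[i]] <- data.frame(cell_id = i, t_min = t,
                           area_um2 = a_true * noise + area_bias,
                           width_um = width)
  }
  do.call(rbind, out)
}

#' Simulate a TMT-like peptide intensity table with known scaling slopes
#'
#' Each entity (protein) receives a true size-scaling slope; every peptide of
#' that entity has channel intensities `base * x_i^slope * noise`, where
#' `x_i = channel_area_i / mean(channel_areas)` is the normalized cell size of
#' channel i and noise is lognormal with coefficient of variation `noise_cv`.
#'
#' @param n_entities number of proteins.
#' @param peptides_per_entity scalar count or vector to sample from.
#' @param true_slopes per-entity slopes; scalar, vector of length `n_entities`,
#'   or NULL to draw from Normal(0, 0.3).
#' @param channel_areas mean cell area per TMT channel, um^2 (>= 2 channels).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates independent replicate tables sharing the true slopes.
#' @param seed integer seed.
#' @return list with `peptides` (data.frame: peptide_id, protein_id, charge,
#'   fraction, replicate, one intensity column per channel), `meta`
#'   (data.frame: channel, area_um2) and `truth` (protein_id, slope).
#' @export
sim_omics <- function(n_entities = 100, peptides_per_entity = 5,
                      true_slopes = NULL, channel_areas = c(2, 3, 4.5, 7, 10),
                      noise_cv = 0.1, n_replicates = 1, seed = NULL) {
  if (n_entities < 1) stop("n_entities must be >= 1")
  if (length(channel_areas) < 2) stop("need >= 2 channels (slope unidentifiable)")
  if (any(channel_areas <= 0)) stop("channel_areas must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_slopes)) true_slopes <- stats::rnorm(n_entities, 0, 0.3)
  true_slopes <- rep_len(true_slopes, n_entities)
  x <- channel_areas / mean(channel_areas)
  sdlog <- sqrt(log(1 + noise_cv^2))
  n_ch <- length(channel_areas)

  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    npep <- if (length(peptides_per_entity) == 1)
      rep(peptides_per_entity, n_entities)
    else sample(peptides_per_entity, n_entities, replace = TRUE)
    for (p in seq_len(n_entities)) {
      base <- stats::rlnorm(npep[p], log(1e5), 1)
      inten <- outer(base, x^true_slopes[p])
      if (noise_cv > 0)
        inten <- inten * matrix(stats::rlnorm(length(inten), -sdlog^2 / 2, sdlog),
                                nrow = npep[p])
      df <- data.frame(
        peptide_id = sprintf("P%04d_pep%02d_r%d", p, seq_len(npep[p]), rep_i),
        protein_id = sprintf("P%04d", p),
        charge = 2L, fraction = 1L, replicate = rep_i)
      colnames(inten) <- paste0("intensity_ch", seq_len(n_ch))
      rows[[length(rows) + 1]] <- cbind(df, as.data.frame(inten))
    }
  }
  list(peptides = do.call(rbind, rows),
       meta = data.frame(channel = paste0("intensity_ch", seq_len(n_ch)),
                         area_um2 = channel_areas),
       truth = data.frame(protein_id = sprintf("P%04d", seq_len(n_entities)),
                          slope = true_slopes))
}

#' Simulate a fluorescence image with spots, nucleoids and cell masks
#'
#' Builds a 2D image as background + isotropic Gaussian spots + smooth
#' elliptical nucleoid blobs, optionally corrupted by Poisson noise
#' (`noise = TRUE` replaces each pixel by a Poisson draw with that mean).
#' Rod-shaped cells are laid out on a grid and returned as a label mask;
#' spots and nucleoids are placed inside cells when any are defined.
#'
#' @param dim image dimensions c(nrow, ncol), pixels.
#' @param n_cells number of rod cells (0 for none; spots then placed anywhere).
#' @param n_spots total number of point spots.
#' @param spot_amplitude,spot_sigma_px spot peak height (a.u.) and SD (px).
#' @param nucleoids_per_cell nucleoid blobs per cell.
#' @param nucleoid_amplitude,nucleoid_sigma_px blob height and SD (px).
#' @param background constant background level, a.u.
#' @param noise logical; apply Poisson noise.
#' @param seed integer seed.
#' @return list with `image` (matrix), `cell_masks` (integer label matrix),
#'   `spots` (data.frame: x_px, y_px, amplitude, sigma_px, cell_id) and
#'   `nucleoids` (data.frame: x_px, y_px, cell_id).
#' @export
sim_images <- function(dim = c(64, 64), n_cells = 0, n_spots = 0,
                       spot_amplitude = 100, spot_sigma_px = 1.2,
                       nucleoids_per_cell = 0, nucleoid_amplitude = 50,
                       nucleoid_sigma_px = 3, background = 10, noise = FALSE,
                       seed = NULL) {
  if (any(dim <= 0)) stop("image dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(background, dim[1], dim[2])
  masks <- matrix(0L, dim[1], dim[2])

  cells <- NULL
  if (n_cells > 0) {
    # rods as axis-aligned rectangles on a grid, 1 px margins
    per_row <- ceiling(sqrt(n_cells))
    ch <- floor(dim[1] / per_row); cw <- floor(dim[2] / ceiling(n_cells / per_row))
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      r0 <- ((i - 1) %% per_row) * ch + 2
      c0 <- ((i - 1) %/% per_row) * cw + 2
      rr <- r0:min(r0 + ch - 3, dim[1]); cc <- c0:min(c0 + cw - 3, dim[2])
      masks[rr, cc] <- i
      cells[[i]] <- list(rows = rr, cols = cc)
    }
  }
  rand_pos <- function(cell_id) {
    if (is.null(cells)) c(stats::runif(1, 3, dim[1] - 2), stats::runif(1, 3, dim[2] - 2))
    else c(stats::runif(1, min(cells[[cell_id]]$rows) + 1, max(cells[[cell_id]]$rows) - 1),
           stats::runif(1, min(cells[[cell_id]]$cols) + 1, max(cells[[cell_id]]$cols) - 1))
  }
  add_gauss <- function(img, x, y, amp, sig) {
    rr <- pmax(1, floor(x - 4 * sig)):pmin(dim[1], ceiling(x + 4 * sig))
    cc <- pmax(1, floor(y - 4 * sig)):pmin(dim[2], ceiling(y + 4 * sig))
    g <- amp * exp(-(outer((rr - x)^2, (cc - y)^2, "+")) / (2 * sig^2))
    img[rr, cc] <- img[rr, cc] + g
    img
  }
  spots <- nucs <- NULL
  if (n_spots > 0) {
    cid <- if (n_cells > 0) rep_len(seq_len(n_cells), n_spots) else rep(NA_integer_, n_spots)
    pos <- t(vapply(seq_len(n_spots), function(i)
      rand_pos(if (is.na(cid[i])) NULL else cid[i]), numeric(2)))
    spots <- data.frame(x_px = pos[, 1], y_px = pos[, 2],
                        amplitude = rep_len(spot_amplitude, n_spots),
                        sigma_px = rep_len(spot_sigma_px, n_spots), cell_id = cid)
    for (i in seq_len(n_spots))
      img <- add_gauss(img, spots$x_px[i], spots$y_px[i], spots$amplitude[i],
                       spots$sigma_px[i])
  }
  if (n_cells > 0 && nucleoids_per_cell > 0) {
    nucs <- do.call(rbind, lapply(seq_len(n_cells), function(ci) {
      # spread nucleoids along the cell long axis so they stay separable
      rr <- range(cells[[ci]]$rows); cc <- range(cells[[ci]]$cols)
      along_rows <- diff(rr) >= diff(cc)
      f <- (seq_len(nucleoids_per_cell) - 0.5) / nucleoids_per_cell
      if (along_rows) data.frame(x_px = rr[1] + f * diff(rr), y_px = mean(cc), cell_id = ci)
      else data.frame(x_px = mean(rr), y_px = cc[1] + f * diff(cc), cell_id = ci)
    }))
    for (i in seq_len(nrow(nucs)))
      img <- add_gauss(img, nucs$x_px[i], nucs$y_px[i], nucleoid_amplitude,
                       nucleoid_sigma_px)
  }
  if (noise) img <- matrix(stats::rpois(length(img), pmax(img, 0)), dim[1], dim[2])
  list(image = img, cell_masks = masks, spots = spots, nucleoids = nucs)
}

#' Simulate two cell populations with prescribed per-bin concentration ratios
#'
#' Population "1N" has per-bin mean concentration `base * true_ratio_per_bin`;
#' population "multiN" has mean `base`, so the 1N/multi-N concentration ratio
#' equals `true_ratio_per_bin` in every bin. Cell areas are uniform within the
#' bin; concentrations carry lognormal noise of coefficient of variation
#' `noise_cv`.
#'
#' @param bin_edges area bin edges, um^2 (length nbins + 1).
#' @param true_ratio_per_bin 1N/multi-N ratio per bin (> 0).
#' @param n_per_bin_a,n_per_bin_b cells per bin per replicate in populations
#'   "1N" and "multiN"; scalar or per-bin vector (> 0).
#' @param base mean multi-N concentration, a.u.
#' @param noise_cv lognormal noise CV.
#' @param n_replicates biological replicates.
#' @param seed integer seed.
#' @return data.frame: area_um2, signal, replicate, population.
#' @export
sim_populations <- function(bin_edges, true_ratio_per_bin, n_per_bin_a,
                            n_per_bin_b, base = 100, noise_cv = 0.2,
                            n_replicates = 1, seed = NULL) {
  nb <- length(bin_edges) - 1
  if (nb < 1) stop("need at least one bin")
  if (any(true_ratio_per_bin <= 0)) stop("ratios must be > 0")
  true_ratio_per_bin <- rep_len(true_ratio_per_bin, nb)
  n_per_bin_a <- rep_len(n_per_bin_a, nb)
  n_per_bin_b <- rep_len(n_per_bin_b, nb)
  if (any(c(n_per_bin_a, n_per_bin_b) < 1)) stop("empty bins not allowed")
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  one <- function(n, mu, rep_i, pop, lo, hi) {
    noise <- if (noise_cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else 1
    data.frame(area_um2 = stats::runif(n, lo, hi), signal = mu * noise,
               replicate = rep_i, population = pop)
  }
  out <- list()
  for (r in seq_len(n_replicates)) for (b in seq_len(nb)) {
    lo <- bin_edges[b]; hi <- bin_edges[b + 1]
    out[[length(out) + 1]] <- one(n_per_bin_a[b], base * true_ratio_per_bin[b],
                                  r, "1N", lo, hi)
    out[[length(out) + 1]] <- one(n_per_bin_b[b], base, r, "multiN", lo, hi)
  }
  do.call(rbind, out)
}
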