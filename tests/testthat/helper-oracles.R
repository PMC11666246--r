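# Independent brute-force apparent diffusion coefficient: plain accumulation
# loop over consecutive-frame displacements, no vectorization shared with the
# implementation.
brute_force_da <- function(track, frame_time) {
  track <- track[order(track$frame), ]
  s <- 0
  n <- 0
  for (i in seq_len(nrow(track) - 1)) {
    if (track$frame[i + 1] - track$frame[i] == 1) {
      s <- s + (track$x_um[i + 1] - track$x_um[i])^2 +
        (track$y_um[i + 1] - track$y_um[i])^2
      n <- n + 1
    }
  }
  if (n == 0) return(NA_real_)
  s / (4 * n * frame_time)
}

# draw apparent-diffusion values whose log10 follows a 3-state Gaussian mixture
sample_log_da_mixture <- function(n, weights, means, sds, seed) {
  set.seed(seed)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  10^stats::rnorm(n, means[comp], sds[comp])
}

# long-time kinetic integration of the explicit three-state RNAP ODEs
# (free/bound/transcribing with promoter depletion); oracle for the
# quasi-steady-state solution in alpha_rnap_B
kinetic_rnap_fraction <- function(R, P, k_on, k_off, k_init, k_term,
                                  t_end = 5000) {
  deriv <- function(t, y, p) {
    B <- y[1]; Tr <- y[2]
    Fr <- R - B - Tr
    Pf <- P - B
    list(c(k_on * Fr * Pf - (k_off + k_init) * B,
           k_init * B - k_term * Tr))
  }
  sol <- deSolve::ode(c(B = 0, Tr = 0), c(0, t_end), deriv, NULL,
                      rtol = 1e-10, atol = 1e-12)
  unname((sol[2, "B"] + sol[2, "Tr"]) / R)
}
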