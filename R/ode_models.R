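#' Parameter set for the DNA-limited expression models
#'
#' Constructs the parameter list shared by model variants A and B. Rates are
#' per minute; concentrations are per um^3 of cell volume; the genome
#' concentration Z is in chromosome copies per um^3. Cell volume and area are
#' proportional to protein number: `V = c * Y`, `A = c_prime * Y`. Defaults
#' are literature-scale values for E. coli in minimal medium (protein number
#' ~3e6 at V ~1 um^3, mRNA lifetime ~5 min, doubling time ~1 h); they are
#' starting points for fitting, not fitted constants.
#'
#' @param r1 bulk transcription rate normalized by total protein number,
#'   1/min.
#' @param r2 bulk translation rate normalized by total protein number, 1/min.
#' @param delta mRNA degradation rate, 1/min.
#' @param K1 half-saturation genome concentration (model A), copies/um^3.
#' @param K2 half-saturation mRNA concentration, molecules/um^3.
#' @param c volume per protein, um^3.
#' @param c_prime area per protein, um^2.
#' @param z_balanced genome concentration under balanced growth (multi-N),
#'   copies/um^3.
#' @param variant "A" (Michaelis-Menten-like active RNAP fraction) or "B"
#'   (mass-action RNAP states: free, promoter-bound, transcribing).
#' @param k_on,k_off,k_init,k_term model-B promoter binding
#'   (per (copies/um^3) per min), unbinding (1/min), initiation (1/min) and
#'   elongation-completion (1/min) rates.
#' @param n_promoter promoter sites per genome copy (model B).
#' @param rnap_conc total RNAP concentration, copies/um^3 (model B), for
#'   balanced growth.
#' @param rnap_profile function(area_um2) -> RNAP concentration in 1N cells
#'   (model B); default a linear increase from `rnap_conc` at 2 um^2 to
#'   2 x `rnap_conc` at 15 um^2, mirroring the observed rise of RNAP
#'   concentration during genome dilution.
#' @return list of class `model_params`.
#' @export
model_params <- function(r1 = 4.2e-4, r2 = 0.016, delta = 0.2, K1 = 1,
                         K2 = 900, c = 3.3e-7, c_prime = 8.3e-7,
                         z_balanced = 1, variant = c("A", "B"),
                         k_on = 2e-3, k_off = 1, k_init = 1, k_term = 1,
                         n_promoter = 1000, rnap_conc = 2000,
                         rnap_profile = NULL) {
  variant <- match.arg(variant)
  if (any(c(r1, r2, delta, K1, K2, k_on, k_off, k_init, k_term) < 0))
    stop("all rates must be >= 0")
  if (c <= 0 || c_prime <= 0) stop("c and c_prime must be > 0")
  if (is.null(rnap_profile))
    rnap_profile <- function(area) rnap_conc * (1 + pmax(0, area - 2) / 13)
  structure(list(r1 = r1, r2 = r2, delta = delta, K1 = K1, K2 = K2, c = c,
                 c_prime = c_prime, z_balanced = z_balanced, variant = variant,
                 k_on = k_on, k_off = k_off, k_init = k_init, k_term = k_term,
                 n_promoter = n_promoter, rnap_conc = rnap_conc,
                 rnap_profile = rnap_profile),
            class = "model_params")
}

#' Active RNAP fraction, model A
#'
#' Michaelis-Menten-like saturation of RNAP activity with genome
#' concentration: `alpha = Z / (K1 + Z)`.
#'
#' @param Z genome concentration, copies/um^3 (>= 0; vectorized).
#' @param K1 half-saturation constant, same units.
#' @return fraction in \[0, 1\].
#' @export
alpha_rnap_A <- function(Z, K1) {
  if (any(Z < 0)) stop("Z must be >= 0")
  Z / (K1 + Z)
}

#' Active ribosome fraction
#'
#' `alpha = X / (K2 + X)` where X is the mRNA concentration.
#'
#' @param X mRNA concentration, molecules/um^3 (>= 0; vectorized).
#' @param K2 half-saturation constant, same units.
#' @return fraction in \[0, 1\].
#' @export
alpha_ribo <- function(X, K2) {
  if (any(X < 0)) stop("X must be >= 0")
  X / (K2 + X)
}

#' Active RNAP fraction, model B (mass-action RNAP states)
#'
#' RNAPs partition into free, promoter-bound and transcribing states by the
#' law of mass action, evaluated at quasi-steady state. Promoter
#' concentration is `n_promoter * Z`; promoter occupancy by bound RNAPs is
#' accounted for, so the fraction responds to the total RNAP concentration
#' (supplied via `rnap_conc`, e.g. the empirically increasing RNAP
#' concentration of 1N cells). "Active" counts bound plus transcribing RNAPs
#' by default (promoter-bound RNAPs remain slow-diffusing, as seen under
#' rifampicin); `active = "transcribing"` counts only transcribing ones.
#'
#' @param Z genome concentration, copies/um^3.
#' @param params a `model_params` (uses k_on, k_off, k_init, k_term,
#'   n_promoter).
#' @param rnap_conc total RNAP concentration, copies/um^3; default
#'   `params$rnap_conc`.
#' @param active "bound_plus_transcribing" (default) or "transcribing".
#' @return fraction in \[0, 1\].
#' @export
alpha_rnap_B <- function(Z, params, rnap_conc = params$rnap_conc,
                         active = c("bound_plus_transcribing", "transcribing")) {
  active <- match.arg(active)
  if (any(Z < 0)) stop("Z must be >= 0")
  P <- params$n_promoter * Z
  R <- rnap_conc
  tau <- if (params$k_term > 0) params$k_init / params$k_term else 0
  denom <- params$k_off + params$k_init
  out <- numeric(length(Z))
  for (i in seq_along(Z)) {
    if (P[i] == 0 || params$k_on == 0 || R <= 0) { out[i] <- 0; next }
    if (denom == 0) {
      # absorbing limit: binding irreversible and never released
      B <- min(R / (1 + tau), P[i])
    } else {
      g <- params$k_on / denom
      # g*(1+tau)*B^2 - (1 + g*R*(1+tau) ... quadratic from B = g*(R-(1+tau)B)*(P-B)
      aa <- g * (1 + tau)
      bb <- -(1 + g * R + g * (1 + tau) * P[i])
      cc <- g * R * P[i]
      disc <- bb^2 - 4 * aa * cc
      B <- if (aa == 0) -cc / bb else (-bb - sqrt(max(disc, 0))) / (2 * aa)
      B <- min(B, R / (1 + tau), P[i])
    }
    Tr <- tau * B
    occ <- if (active == "bound_plus_transcribing") (B + Tr) / R else Tr / R
    if (occ > 1 + 1e-9) stop("non-physical RNAP occupancy > 1")
    out[i] <- min(occ, 1)
  }
  out
}

.alpha_rnap <- function(Z, params, area = NULL, genome_law = "multiN") {
  if (params$variant == "A") return(alpha_rnap_A(Z, params$K1))
  rconc <- if (genome_law == "oneN" && !is.null(area))
    params$rnap_profile(area) else params$rnap_conc
  alpha_rnap_B(Z, params, rnap_conc = rconc)
}

#' Simulate the DNA-limited expression model
#'
#' Integrates `dX/dt = r1 * alpha_RNAP * Y - delta * X` and
#' `dY/dt = r2 * alpha_ribo * Y` (mRNA number X, protein number Y) with a
#' Bogacki-Shampine (ode23-type) adaptive solver at rtol 1e-4 / atol 1e-5.
#' Under the `multiN` genome law Z is constant (`z_balanced`: genome copies
#' scale with volume); under `oneN` the cell keeps a single genome copy so
#' `Z(t) = 1 / (c * Y(t))` dilutes as the cell grows. dY/dt is the absolute
#' growth rate and (1/Y) dY/dt the relative growth rate of the model.
#'
#' @param params a `model_params`.
#' @param genome_law "multiN" or "oneN".
#' @param X0,Y0 initial mRNA and protein numbers (> 0). Defaults come from
#'   [balanced_growth_init()] at `Y0 = 2.5 um^2 / c_prime` when NULL.
#' @param t_end,dt_out simulation span and output interval, min.
#' @return data.frame of class `model_trajectory`: t_min, X, Y, V_um3, A_um2,
#'   Z, alpha_rnap, alpha_ribo, dYdt, dAdt_um2_min, rel_rate_per_min.
#' @export
simulate_model <- function(params, genome_law = c("multiN", "oneN"),
                           X0 = NULL, Y0 = NULL, t_end = 300, dt_out = 1) {
  genome_law <- match.arg(genome_law)
  if (is.null(X0) || is.null(Y0)) {
    init <- balanced_growth_init(params, Y_target = 2.5 / params$c_prime)
    if (is.null(X0)) X0 <- init["X"]
    if (is.null(Y0)) Y0 <- init["Y"]
  }
  if (X0 <= 0 || Y0 <= 0) stop("initial conditions must be positive")
  deriv <- function(t, state, p) {
    # adaptive steps can transiently undershoot zero; clamp for the rates
    X <- max(state[1], 0); Y <- max(state[2], .Machine$double.xmin)
    V <- p$c * Y
    Z <- if (genome_law == "multiN") p$z_balanced else 1 / V
    aR <- .alpha_rnap(Z, p, area = p$c_prime * Y, genome_law = genome_law)
    ar <- alpha_ribo(X / V, p$K2)
    list(c(p$r1 * aR * Y - p$delta * X, p$r2 * ar * Y))
  }
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::ode(c(X = unname(X0), Y = unname(Y0)), times, deriv, params,
                      method = "ode23", rtol = 1e-4, atol = 1e-5)
  if (attr(sol, "istate")[1] < 0) stop("solver failure; state: ",
                                       paste(utils::tail(sol, 1), collapse = " "))
  X <- pmax(sol[, "X"], 0); Y <- sol[, "Y"]
  V <- params$c * Y
  Z <- if (genome_law == "multiN") rep(params$z_balanced, length(Y)) else 1 / V
  aR <- vapply(seq_along(Y), function(i)
    .alpha_rnap(Z[i], params, area = params$c_prime * Y[i],
                genome_law = genome_law), numeric(1))
  ar <- alpha_ribo(X / V, params$K2)
  dYdt <- params$r2 * ar * Y
  out <- data.frame(t_min = sol[, "time"], X = X, Y = Y, V_um3 = V,
                    A_um2 = params$c_prime * Y, Z = Z, alpha_rnap = aR,
                    alpha_ribo = ar, dYdt = dYdt,
                    dAdt_um2_min = params$c_prime * dYdt,
                    rel_rate_per_min = dYdt / Y)
  class(out) <- c("model_trajectory", class(out))
  out
}

#' Balanced-growth initial condition
#'
#' Integrates the model under the multi-N (constant genome concentration)
#' law until the mRNA-to-protein ratio X/Y stabilizes (relative change below
#' `tol` per integration chunk), then rescales the state so that Y equals
#' `Y_target` while preserving X/Y. At balanced growth the ratio satisfies
#' X/Y = r1 * alpha_RNAP / (lambda + delta) with lambda = r2 * alpha_ribo.
#'
#' @param params a `model_params`.
#' @param Y_target protein number to rescale to.
#' @param X0_frac starting guess for X as a fraction of Y. Default 1e-3.
#' @param tol relative X/Y change per chunk declaring convergence.
#' @param chunk_min integration chunk, min.
#' @param max_chunks failure bound.
#' @return named vector c(X, Y).
#' @export
balanced_growth_init <- function(params, Y_target, X0_frac = 1e-3,
                                 tol = 1e-8, chunk_min = 500,
                                 max_chunks = 200) {
  if (params$r2 <= 0) stop("params must admit growth (r2 > 0)")
  state <- c(X = X0_frac * Y_target, Y = Y_target)
  ratio <- state["X"] / state["Y"]
  for (i in seq_len(max_chunks)) {
    tr <- simulate_model(params, "multiN", X0 = state["X"], Y0 = state["Y"],
                         t_end = chunk_min, dt_out = chunk_min)
    n <- nrow(tr)
    state <- c(X = tr$X[n], Y = tr$Y[n])
    # keep numbers bounded: only the ratio matters on the balanced manifold
    scale <- Y_target / state["Y"]
    state <- state * scale
    new_ratio <- state["X"] / state["Y"]
    if (abs(new_ratio - ratio) <= tol * ratio) {
      return(c(X = unname(state["X"]), Y = unname(state["Y"])))
    }
    ratio <- new_ratio
  }
  stop("balanced growth did not converge within max_chunks")
}

#' Model predictions for the six observable datasets
#'
#' Growth rate (dA/dt), active RNAP fraction and active ribosome fraction as
#' functions of cell area, for both 1N and multi-N genome laws, evaluated at
#' the requested areas. Multi-N cells are in balanced growth (growth rate
#' proportional to area, constant fractions); 1N curves come from a single
#' genome-dilution trajectory started from balanced growth at the smallest
#' requested area.
#'
#' @param params a `model_params`.
#' @param areas_1N,areas_multiN cell areas, um^2.
#' @param t_end 1N simulation span, min.
#' @return named list of data.frames (area_um2, value): growth_1N,
#'   growth_multiN, alpha_rnap_1N, alpha_rnap_multiN, alpha_ribo_1N,
#'   alpha_ribo_multiN.
#' @export
predict_six_curves <- function(params, areas_1N, areas_multiN, t_end = 1500) {
  init <- balanced_growth_init(params, Y_target = min(areas_1N) / params$c_prime)
  bal <- simulate_model(params, "multiN", X0 = init["X"], Y0 = init["Y"],
                        t_end = 5, dt_out = 5)
  lambda <- bal$rel_rate_per_min[1]
  aR_bal <- bal$alpha_rnap[1]; ar_bal <- bal$alpha_ribo[1]
  one <- simulate_model(params, "oneN", X0 = init["X"], Y0 = init["Y"],
                        t_end = t_end, dt_out = 2)
  if (max(one$A_um2) < max(areas_1N))
    one <- simulate_model(params, "oneN", X0 = init["X"], Y0 = init["Y"],
                          t_end = 4 * t_end, dt_out = 4)
  f <- function(col) stats::approx(one$A_um2, one[[col]], xout = areas_1N,
                                   rule = 2)$y
  list(growth_1N = data.frame(area_um2 = areas_1N, value = f("dAdt_um2_min")),
       growth_multiN = data.frame(area_um2 = areas_multiN,
                                  value = lambda * areas_multiN),
       alpha_rnap_1N = data.frame(area_um2 = areas_1N, value = f("alpha_rnap")),
       alpha_rnap_multiN = data.frame(area_um2 = areas_multiN, value = aR_bal),
       alpha_ribo_1N = data.frame(area_um2 = areas_1N, value = f("alpha_ribo")),
       alpha_ribo_multiN = data.frame(area_um2 = areas_multiN, value = ar_bal))
}

#' Fit model parameters to six observed curves
#'
#' Weighted least squares over the six datasets (growth rate, active RNAP
#' fraction and active ribosome fraction, each for 1N and multi-N cells),
#' minimized by derivative-free Nelder-Mead multistart on log-transformed
#' free parameters. By default r2 is held fixed (it is set by the absolute
#' growth-rate scale) and r1, delta, K1, K2 are free.
#'
#' @param datasets named list of data.frames (area_um2, value, sd) with the
#'   names of [predict_six_curves()] output; `sd` defaults to 1 if absent.
#' @param params0 starting `model_params`.
#' @param free character vector of free parameter names.
#' @param n_starts number of multistarts (start 1 is params0, the rest are
#'   lognormal perturbations). Default 20.
#' @param perturb_sd sdlog of the multistart perturbations.
#' @param seed integer seed for the multistarts.
#' @return list: params (fitted `model_params`), objective, residuals (named
#'   list of per-dataset weighted residual vectors), convergence,
#'   underdetermined (TRUE when only one genome law is represented, e.g. K1
#'   is unidentifiable when Z never varies).
#' @export
fit_model_params <- function(datasets, params0,
                             free = c("r1", "delta", "K1", "K2"),
                             n_starts = 20, perturb_sd = 0.3, seed = 1) {
  laws <- c(any(grepl("_1N$", names(datasets))),
            any(grepl("_multiN$", names(datasets))))
  underdetermined <- !all(laws)
  areas_1N <- if (laws[1])
    datasets[[grep("_1N$", names(datasets))[1]]]$area_um2
  else datasets[[1]]$area_um2
  areas_multiN <- if (laws[2])
    datasets[[grep("_multiN$", names(datasets))[1]]]$area_um2
  else datasets[[1]]$area_um2
  obj <- function(logp) {
    p <- params0
    p[free] <- as.list(exp(logp))
    val <- try({
      pred <- predict_six_curves(p, areas_1N, areas_multiN)
      s <- 0
      for (nm in names(datasets)) {
        d <- datasets[[nm]]
        sd <- if ("sd" %in% names(d)) d$sd else 1
        s <- s + sum(((pred[[nm]]$value - d$value) / sd)^2)
      }
      s
    }, silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) 1e12 else val
  }
  start0 <- log(unlist(params0[free]))
  if (!is.finite(obj(start0))) stop("objective non-finite at params0")
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) start0 else start0 + stats::rnorm(length(start0), 0, perturb_sd)
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  pbest <- params0
  pbest[free] <- as.list(exp(best$par))
  pred <- try(predict_six_curves(pbest, areas_1N, areas_multiN), silent = TRUE)
  resid <- if (inherits(pred, "try-error")) NULL else {
    r <- lapply(names(datasets), function(nm) {
      d <- datasets[[nm]]
      sd <- if ("sd" %in% names(d)) d$sd else 1
      (pred[[nm]]$value - d$value) / sd
    })
    names(r) <- names(datasets)
    r
  }
  list(params = pbest, objective = best$value, residuals = resid,
       convergence = best$convergence, underdetermined = underdetermined)
}

#' Minimal genome concentration that limits transcription
#'
#' The cell area at which total active RNAPs deviate from the wild-type
#' scaling, observed in cells carrying `genome_copies` chromosome copies,
#' implies a limiting concentration of `genome_copies / deviation_area`
#' chromosome copies per um^2.
#'
#' @param deviation_area cell area at deviation, um^2 (> 0).
#' @param genome_copies chromosome copies in the deviating cells. Default 1.
#' @return copies per um^2.
#' @export
estimate_limiting_concentration <- function(deviation_area, genome_copies = 1) {
  if (any(deviation_area <= 0)) stop("deviation_area must be > 0")
  genome_copies / deviation_area
}

#' Detect where a 1N scaling curve deviates from the WT linear fit
#'
#' Returns the smallest bin center at which the 1N binned curve falls below
#' `(1 - threshold)` times the WT linear fit through the origin and stays
#' below for all larger bins; NA when no such sustained deviation exists.
#'
#' @param curve data.frame: bin_center_um2 (or area_um2), value (or mean).
#' @param wt_slope slope of the WT linear fit through the origin.
#' @param threshold relative deficit declaring deviation. Default 0.1.
#' @return deviation area, um^2, or NA.
#' @export
detect_deviation_area <- function(curve, wt_slope, threshold = 0.1) {
  a <- curve[[intersect(c("bin_center_um2", "area_um2"), names(curve))[1]]]
  v <- curve[[intersect(c("value", "mean"), names(curve))[1]]]
  o <- order(a); a <- a[o]; v <- v[o]
  below <- v < (1 - threshold) * wt_slope * a
  sustained <- rev(cumprod(rev(below))) == 1
  if (!any(sustained)) return(NA_real_)
  a[which(sustained)[1]]
}
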