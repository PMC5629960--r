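#' Default constituent band model
#'
#' Gaussian absorption bands per constituent, placed at the main NIR
#' absorption features of dried forage (C-H, N-H and O-H combination and
#' overtone bands near 4,240, 4,740, 5,170, 5,800 and 6,800 cm^-1).
#' Amplitudes are absorbance units per %DM, sized so that spectra at
#' realistic concentrations stay in the typical log(1/R) range of ground
#' plant material.
#'
#' @return Named list (CP, NDF, ADF, WSC) of data.frames with columns
#'   `center` (cm^-1), `width` (cm^-1, Gaussian sd) and `amplitude`
#'   (absorbance per %DM).
#' @export
default_band_model <- function() {
  list(
    CP = data.frame(center = c(4740, 6510),
                    width = c(90, 150),
                    amplitude = c(0.010, 0.004)),
    NDF = data.frame(center = c(4240, 5800),
                     width = c(80, 120),
                     amplitude = c(0.005, 0.003)),
    ADF = data.frame(center = c(4240, 4860),
                     width = c(70, 100),
                     amplitude = c(0.002, 0.004)),
    WSC = data.frame(center = c(4390, 5170, 6800),
                     width = c(80, 120, 200),
                     amplitude = c(0.006, 0.003, 0.002)))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of an FT-NIR forage-quality
#' calibration set: 123 samples on a 4,000-12,500 cm^-1 grid with 2,203
#' points, constituent concentrations uniform within the observed field
#' ranges (CP 4.45-30.60, NDF 21.29-60.47, ADF 11.66-36.17,
#' WSC 3.95-51.52 %DM), per-sample multiplicative and additive scatter with
#' a mild baseline tilt, white absorbance noise, and three laboratory
#' replicates per sample with 1.5 %DM replicate noise (the SEL scale of
#' routine wet chemistry).
#'
#' @param n_samples number of samples.
#' @param wn_min,wn_max,n_points wavenumber grid specification.
#' @param ranges named list of `c(min, max)` concentration ranges (%DM).
#' @param scatter_mult_sd sd of the per-sample multiplicative scatter factor
#'   (around 1).
#' @param scatter_add_sd sd of per-sample additive offsets (absorbance).
#' @param scatter_slope_sd sd of the per-sample linear baseline slope
#'   (absorbance over the full grid).
#' @param noise_sd sd of white absorbance noise per point.
#' @param n_replicates laboratory replicates per sample (>= 2 for SEL).
#' @param replicate_sd within-sample laboratory sd (%DM).
#' @param correlation optional constituent correlation matrix (Gaussian
#'   copula); NULL = independent draws.
#' @param seed mandatory integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 123,
                       wn_min = 4000, wn_max = 12500, n_points = 2203,
                       ranges = list(CP = c(4.45, 30.60),
                                     NDF = c(21.29, 60.47),
                                     ADF = c(11.66, 36.17),
                                     WSC = c(3.95, 51.52)),
                       scatter_mult_sd = 0.10,
                       scatter_add_sd = 0.05,
                       scatter_slope_sd = 0.01,
                       noise_sd = 0.002,
                       n_replicates = 3,
                       replicate_sd = 1.5,
                       correlation = NULL,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_points < 2 || wn_max <= wn_min) stop("degenerate wavenumber grid")
  for (r in ranges)
    if (r[1] < 0 || r[2] > 100 || r[1] >= r[2])
      stop("concentration ranges must be within [0, 100] with min < max")
  sds <- c(scatter_mult_sd, scatter_add_sd, scatter_slope_sd, noise_sd,
           replicate_sd)
  if (any(sds < 0)) stop("all sds must be >= 0")
  structure(list(n_samples = n_samples, wn_min = wn_min, wn_max = wn_max,
                 n_points = n_points, ranges = ranges,
                 scatter_mult_sd = scatter_mult_sd,
                 scatter_add_sd = scatter_add_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 noise_sd = noise_sd, n_replicates = n_replicates,
                 replicate_sd = replicate_sd, correlation = correlation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate a constituent's band profile on a wavenumber grid
band_profile <- function(bands, wn) {
  prof <- numeric(length(wn))
  for (i in seq_len(nrow(bands)))
    prof <- prof + bands$amplitude[i] *
      exp(-0.5 * ((wn - bands$center[i]) / bands$width[i])^2)
  prof
}

# Broad common background of dried plant material: offset plus a wide
# water-related hump; absorbed by centering/scatter correction downstream.
background_profile <- function(wn) {
  0.30 + 0.20 * exp(-0.5 * ((wn - 5170) / 900)^2)
}

#' Simulate a forage NIRS data set
#'
#' Beer-Lambert band-model generator.  Per sample i and wavenumber v:
#' `A_i(v) = b_i * (sum_c conc_ic * band_c(v) + bg(v) + base_i +
#' slope_i * u(v)) + a_i + eps_i(v)` with `u(v)` the grid position scaled to
#' `[0, 1]`, multiplicative scatter `b_i ~ N(1, scatter_mult_sd)`, additive
#' terms `base_i, a_i ~ N(0, scatter_add_sd)`, tilt
#' `slope_i ~ N(0, scatter_slope_sd)` and white noise
#' `eps ~ N(0, noise_sd)`.  Concentrations are uniform within the
#' configured ranges (optionally correlated through a Gaussian copula).
#' Laboratory replicate values are truth plus `N(0, replicate_sd)` noise;
#' the reference table's per-sample value is the generating truth and the
#' replicates feed the SEL estimator.  Fully reproducible from the seed.
#'
#' @param cfg a [sim_config].
#' @param bands a band model (see [default_band_model]).
#' @return list with `spectra` ([spectra_set]), `reference`
#'   (`reference_table` with replicate-resolved attribute), `replicates`
#'   (long data.frame `sample_id, replicate, <constituents>`) and `truth`
#'   (concentrations and per-sample scatter parameters).
#' @export
simulate_nirs <- function(cfg, bands = default_band_model()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  wn <- seq(cfg$wn_min, cfg$wn_max, length.out = cfg$n_points)
  params <- names(cfg$ranges)
  missing_bands <- setdiff(params, names(bands))
  if (length(missing_bands))
    stop("no band model for constituent(s): ",
         paste(missing_bands, collapse = ", "))
  # concentrations: uniform marginals, optional Gaussian-copula correlation
  P <- length(params)
  if (is.null(cfg$correlation)) {
    U <- matrix(stats::runif(n * P), n, P)
  } else {
    R <- as.matrix(cfg$correlation)
    stopifnot(nrow(R) == P, ncol(R) == P)
    Z <- matrix(stats::rnorm(n * P), n, P) %*% chol(R)
    U <- stats::pnorm(Z)
  }
  conc <- sapply(seq_along(params), function(j) {
    r <- cfg$ranges[[j]]
    r[1] + U[, j] * (r[2] - r[1])
  })
  colnames(conc) <- params
  profiles <- sapply(params, function(p) band_profile(bands[[p]], wn))
  bg <- background_profile(wn)
  u <- (wn - cfg$wn_min) / (cfg$wn_max - cfg$wn_min)
  b <- 1 + stats::rnorm(n, 0, cfg$scatter_mult_sd)
  b[b < 0.2] <- 0.2  # keep the physical scatter factor positive
  base <- stats::rnorm(n, 0, cfg$scatter_add_sd)
  a_off <- stats::rnorm(n, 0, cfg$scatter_add_sd)
  slope <- stats::rnorm(n, 0, cfg$scatter_slope_sd)
  clean <- conc %*% t(profiles)           # n x p chemical signal
  A <- b * (clean + rep(1, n) %*% t(bg) + base + outer(slope, u)) + a_off
  if (cfg$noise_sd > 0)
    A <- A + matrix(stats::rnorm(n * length(wn), 0, cfg$noise_sd),
                    n, length(wn))
  ids <- sprintf("S%03d", seq_len(n))
  rownames(A) <- ids
  spectra <- spectra_set(A, wn, ids)
  # laboratory replicates: truth + replicate noise
  reps <- do.call(rbind, lapply(seq_len(cfg$n_replicates), function(r) {
    d <- data.frame(sample_id = ids, replicate = r)
    for (p in params)
      d[[p]] <- pmin(100, pmax(0,
        conc[, p] + stats::rnorm(n, 0, cfg$replicate_sd)))
    d
  }))
  reps <- reps[order(reps$sample_id, reps$replicate), ]
  rownames(reps) <- NULL
  ref <- data.frame(sample_id = ids, conc, check.names = FALSE)
  ref <- reference_table(ref)
  attr(ref, "replicates") <- reps
  truth <- data.frame(sample_id = ids, conc,
                      scatter_mult = b, scatter_add = a_off,
                      scatter_base = base, scatter_slope = slope,
                      check.names = FALSE)
  list(spectra = spectra, reference = ref, replicates = reps, truth = truth)
}

#' End-to-end parameter-recovery experiment
#'
#' Harness over the whole pipeline: simulate, range-split, cross-validate
#' the given pretreatment, fit at the chosen rank and report calibration and
#' external-validation statistics for one constituent.
#'
#' @param cfg a [sim_config].
#' @param spec a [pretreatment_spec].
#' @param max_rank maximum PLS rank for cross-validation.
#' @param parameter constituent to model (default "CP").
#' @param bands band model.
#' @param val_fraction validation share of samples (default 30/123, the
#'   conventional range-split ratio).
#' @param scheme,k cross-validation scheme (default contiguous 10-fold).
#' @return list with `calibration` and `validation` `eval_report`s, the
#'   fitted `model` and the `cv_result`.
#' @export
recovery_experiment <- function(cfg, spec, max_rank, parameter = "CP",
                                bands = default_band_model(),
                                val_fraction = 30 / 123,
                                scheme = "kfold", k = 10) {
  sim <- simulate_nirs(cfg, bands)
  n <- cfg$n_samples
  n_val <- max(2, round(n * val_fraction))
  split <- range_split(sim$reference, n - n_val, n_val)
  s_cal <- sim$spectra[split$calibration_ids, ]
  y_cal <- sim$reference[[parameter]][
    match(split$calibration_ids, sim$reference$sample_id)]
  pre <- apply_pretreatment(s_cal, spec)
  cv <- cross_validate(pre$spectra$absorbance, y_cal, max_rank,
                       scheme = scheme, k = k)
  model <- fit_calibration(s_cal, y_cal, spec, cv$rank, parameter)
  rep <- build_report(model, cv, split, sim$spectra, sim$reference,
                      replicates = sim$replicates)
  c(rep, list(model = model, cv = cv))
}
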