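#' Configuration for synthetic patch-clamp fluorometry datasets
#'
#' Describes a cohort of excised-patch recordings generated from a known
#' ("truth") dose-response model. In \code{"hill"} mode each patch draws its
#' own log10 IC50 from Normal(population, between-patch SD) while the Hill
#' slope and Imax are shared; only currents are emitted. In \code{"mwc"} mode
#' all patches share the (L, KA, D) truth and each application also carries
#' an emission spectrum whose ANAP peak is scaled by (1 - site occupancy) and
#' bleaches exponentially; a barium application terminates the protocol to
#' define the zero-current level.
#'
#' @param construct_label construct name carried through to the tables.
#' @param model_kind \code{"hill"} or \code{"mwc"}.
#' @param truth generating parameters: for hill,
#'   \code{list(log10_ic50, between_patch_sd, h, imax)}; for mwc,
#'   \code{list(L, KA, D)}.
#' @param concentrations test concentrations in molar (>= 0).
#' @param n_patches number of patches.
#' @param current_noise_sd SD of the multiplicative amplitude jitter applied
#'   per solution application (fractional; default 0.03).
#' @param quench_noise_sd SD of spectral intensity noise, as a fraction of the
#'   ANAP peak amplitude (default 0.03).
#' @param rundown_per_application fractional current lost per solution
#'   application (multiplicative decay; default 0.02).
#' @param bleach_tau single-exponential photobleach time constant, s
#'   (default 60).
#' @param anap_center,gfp_center,peak_width emission peak positions and
#'   common Gaussian width, nm. The GFP peak is truncated below 490 nm
#'   (sharp blue emission edge), so it does not leak into the ANAP band.
#' @param seed integer seed.
#' @param i0_pA patch current amplitude before rundown (default 200 pA).
#' @param offset_pA true zero-current offset added to all current samples
#'   (default 5 in mwc mode, 0 in hill mode).
#' @param app_duration_s seconds per solution application (default 2).
#' @param sampling_rate_hz current sampling rate (default 100).
#' @return validated config of class \code{"pcf_config"}.
#' @export
pcf_config <- function(construct_label = "Kir6.2+SUR1",
                       model_kind = c("hill", "mwc"),
                       truth = list(),
                       concentrations = 10^seq(-6, -3, length.out = 7),
                       n_patches = 8,
                       current_noise_sd = 0.03, quench_noise_sd = 0.03,
                       rundown_per_application = 0.02, bleach_tau = 60,
                       anap_center = 470, gfp_center = 510, peak_width = 15,
                       seed = 1, i0_pA = 200, offset_pA = NULL,
                       app_duration_s = 2, sampling_rate_hz = 100) {
  model_kind <- match.arg(model_kind)
  defaults <- if (model_kind == "hill")
    list(log10_ic50 = -4.5, between_patch_sd = 0.05, h = 1, imax = 1)
  else list(L = 1, KA = 1e5, D = 0.1)
  truth <- utils::modifyList(defaults, truth)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (current_noise_sd < 0 || quench_noise_sd < 0)
    stop("noise SDs must be >= 0")
  if (rundown_per_application < 0 || rundown_per_application >= 1)
    stop("rundown_per_application must be in [0, 1)")
  if (model_kind == "hill") {
    if (truth$imax < 0 || truth$imax > 1) stop("truth imax must be in [0, 1]")
    if (truth$between_patch_sd < 0) stop("between_patch_sd must be >= 0")
  } else {
    check_mwc_params(truth$L, truth$KA, truth$D)
  }
  if (is.null(offset_pA)) offset_pA <- if (model_kind == "mwc") 5 else 0
  stopifnot(n_patches >= 1, bleach_tau > 0, i0_pA > 0, app_duration_s > 0,
            sampling_rate_hz > 0)
  structure(list(construct_label = construct_label, model_kind = model_kind,
                 truth = truth, concentrations = concentrations,
                 n_patches = as.integer(n_patches),
                 current_noise_sd = current_noise_sd,
                 quench_noise_sd = quench_noise_sd,
                 rundown_per_application = rundown_per_application,
                 bleach_tau = bleach_tau, anap_center = anap_center,
                 gfp_center = gfp_center, peak_width = peak_width,
                 seed = as.integer(seed), i0_pA = i0_pA,
                 offset_pA = offset_pA, app_duration_s = app_duration_s,
                 sampling_rate_hz = sampling_rate_hz),
            class = "pcf_config")
}

gauss_peak <- function(lambda, center, width) exp(-0.5 * ((lambda - center) / width)^2)

make_spectrum <- function(cfg, t, occ, anap_amp, gfp_amp, background,
                          noisy = TRUE) {
  lambda <- background$wavelength
  anap <- anap_amp * (1 - occ) * exp(-t / cfg$bleach_tau) *
    gauss_peak(lambda, cfg$anap_center, cfg$peak_width)
  gfp <- gfp_amp * gauss_peak(lambda, cfg$gfp_center, cfg$peak_width)
  gfp[lambda < 490] <- 0                  # sharp blue edge of GFP emission
  intensity <- anap + gfp + background$intensity
  if (noisy && cfg$quench_noise_sd > 0)
    intensity <- intensity +
      stats::rnorm(length(lambda), 0, cfg$quench_noise_sd * anap_amp)
  list(time = t, wavelength = lambda, intensity = intensity)
}

#' Generate a synthetic patch-clamp fluorometry dataset
#'
#' Per patch, an alternating control/test/control protocol over the
#' configured concentrations, with multiplicative rundown per solution
#' application, per-application amplitude jitter and additive sample noise on
#' the currents; in mwc mode, one background-contaminated emission spectrum
#' per application (1 s exposure at the application midpoint) with
#' exponential ANAP photobleaching, and a terminal barium application that
#' defines the zero-current level. All randomness is governed by the config
#' seed.
#'
#' @param cfg a \code{\link{pcf_config}}.
#' @return list with \code{recordings} (list of \code{patch_recording}
#'   objects: \code{patch_id}, \code{construct}, \code{applications} table,
#'   \code{currents} samples per application, \code{spectra},
#'   \code{background}, \code{sampling_rate}) and \code{truth} (data.frame of
#'   generating fractional current/quenching per patch and concentration).
#' @export
gen_pcf_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "pcf_config"))
  set.seed(cfg$seed)
  lambda <- seq(400, 600, by = 1)
  background <- list(wavelength = lambda,
                     intensity = 50 + 0.05 * (lambda - 400))
  n_samp <- round(cfg$app_duration_s * cfg$sampling_rate_hz)
  recordings <- vector("list", cfg$n_patches)
  truth_rows <- list()
  for (p in seq_len(cfg$n_patches)) {
    if (cfg$model_kind == "hill") {
      l10 <- stats::rnorm(1, cfg$truth$log10_ic50, cfg$truth$between_patch_sd)
      f_cur <- function(c) hill_fraction(c, l10, cfg$truth$h, cfg$truth$imax)
      f_occ <- NULL
    } else {
      l10 <- NA_real_
      f_cur <- function(c) mwc_current(c, cfg$truth$L, cfg$truth$KA,
                                       cfg$truth$D)
      f_occ <- function(c) mwc_occupancy(c, cfg$truth$L, cfg$truth$KA,
                                         cfg$truth$D)
    }
    concs <- cfg$concentrations
    sol <- c(rbind(rep("control", length(concs)), rep("test", length(concs))),
             "control")
    conc <- c(rbind(rep(0, length(concs)), concs), 0)
    if (cfg$model_kind == "mwc") { sol <- c(sol, "barium"); conc <- c(conc, 0) }
    n_app <- length(sol)
    t_start <- (seq_len(n_app) - 1) * cfg$app_duration_s
    apps <- data.frame(app = seq_len(n_app), solution = sol, conc = conc,
                       t_start = t_start,
                       t_end = t_start + cfg$app_duration_s)
    anap_amp <- 1000; gfp_amp <- 800
    currents <- vector("list", n_app)
    spectra <- if (cfg$model_kind == "mwc") vector("list", n_app) else NULL
    for (k in seq_len(n_app)) {
      amp <- cfg$i0_pA * (1 - cfg$rundown_per_application)^(k - 1)
      jit <- if (cfg$current_noise_sd > 0)
        1 + stats::rnorm(1, 0, cfg$current_noise_sd) else 1
      true_mean <- switch(sol[k],
                          control = amp,
                          test = amp * f_cur(conc[k]),
                          barium = 0)
      currents[[k]] <- true_mean * jit + cfg$offset_pA +
        if (cfg$current_noise_sd > 0) stats::rnorm(n_samp, 0, 1) else
          rep(0, n_samp)
      if (cfg$model_kind == "mwc" && sol[k] != "barium") {
        occ <- if (sol[k] == "test") f_occ(conc[k]) else 0
        spectra[[k]] <- make_spectrum(cfg, mean(c(apps$t_start[k],
                                                  apps$t_end[k])),
                                      occ, anap_amp, gfp_amp, background,
                                      noisy = cfg$quench_noise_sd > 0)
      }
    }
    recordings[[p]] <- structure(
      list(patch_id = sprintf("patch%02d", p), construct = cfg$construct_label,
           applications = apps, currents = currents, spectra = spectra,
           background = background, sampling_rate = cfg$sampling_rate_hz),
      class = "patch_recording")
    truth_rows[[p]] <- data.frame(
      patch = sprintf("patch%02d", p), construct = cfg$construct_label,
      conc = concs,
      frac_current_true = f_cur(concs),
      frac_quench_true = if (is.null(f_occ)) NA_real_ else f_occ(concs),
      patch_log10_ic50 = l10)
  }
  list(recordings = recordings, truth = do.call(rbind, truth_rows))
}

#' Generate a tidy synthetic dose-response table directly
#'
#' Shortcut past the raw-recording layer: draws per-patch log10 IC50 values
#' and emits (patch, concentration, fractional current) rows with Gaussian
#' observation noise applied directly to the fractional currents. This is the
#' generating process the hierarchical Hill model assumes, useful for
#' parameter-recovery experiments at an exactly specified noise SD.
#'
#' @param log10_ic50 population log10 IC50 (log10 molar).
#' @param n_patches number of patches.
#' @param concentrations test concentrations, molar.
#' @param h,imax shared Hill slope and maximal inhibited fraction.
#' @param between_patch_sd between-patch SD of log10 IC50.
#' @param noise_sd Gaussian observation noise SD on fractional current.
#' @param seed integer seed.
#' @param construct construct label.
#' @return list with \code{table} (data.frame: patch, construct, conc,
#'   frac_current) and \code{patch_log10_ic50} (the true per-patch values).
#' @export
gen_hill_table <- function(log10_ic50, n_patches = 8,
                           concentrations = 10^seq(-6, -3, length.out = 7),
                           h = 1, imax = 1, between_patch_sd = 0.05,
                           noise_sd = 0.03, seed = 1,
                           construct = "construct") {
  set.seed(as.integer(seed))
  rows <- list()
  patch_true <- stats::rnorm(n_patches, log10_ic50, between_patch_sd)
  for (p in seq_len(n_patches)) {
    f <- hill_fraction(concentrations, patch_true[p], h, imax)
    rows[[p]] <- data.frame(
      patch = sprintf("patch%02d", p), construct = construct,
      conc = concentrations,
      frac_current = f + stats::rnorm(length(f), 0, noise_sd))
  }
  list(table = do.call(rbind, rows), patch_log10_ic50 = patch_true)
}
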