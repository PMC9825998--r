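# Spectra are lists with numeric `wavelength` (nm, ascending) and `intensity`
# (counts) of equal length, plus optionally `time` (s).

check_spectrum <- function(s, name = "spectrum") {
  if (!is.list(s) || is.null(s$wavelength) || is.null(s$intensity))
    stop(name, " must be a list with wavelength and intensity")
  if (length(s$wavelength) != length(s$intensity))
    stop(name, ": wavelength and intensity lengths differ")
  if (is.unsorted(s$wavelength, strictly = TRUE))
    stop(name, ": wavelength grid must be strictly ascending")
  invisible(TRUE)
}

#' Subtract a background spectrum
#'
#' Pointwise difference on identical wavelength grids. Negative corrected
#' intensities (noise) are preserved as-is.
#'
#' @param spectrum,background spectra (lists with \code{wavelength},
#'   \code{intensity}).
#' @return corrected spectrum (same structure as \code{spectrum}).
#' @export
subtract_background <- function(spectrum, background) {
  check_spectrum(spectrum); check_spectrum(background, "background")
  if (length(spectrum$wavelength) != length(background$wavelength) ||
      any(spectrum$wavelength != background$wavelength))
    stop("spectrum and background wavelength grids differ")
  spectrum$intensity <- spectrum$intensity - background$intensity
  spectrum
}

#' Mean intensity over a wavelength band
#'
#' Averages the intensity over all grid points inside the band (inclusive
#' ends). The default band, 469.5 to 474.5 nm, brackets the ANAP emission
#' peak at ~470 nm.
#'
#' @param spectrum a spectrum.
#' @param band \code{c(lo, hi)} in nm.
#' @return mean intensity (scalar).
#' @export
anap_band_intensity <- function(spectrum, band = c(469.5, 474.5)) {
  check_spectrum(spectrum)
  sel <- spectrum$wavelength >= band[1] & spectrum$wavelength <= band[2]
  if (!any(sel))
    stop("no wavelength grid point falls inside the band [",
         band[1], ", ", band[2], "] nm")
  mean(spectrum$intensity[sel])
}

#' Photobleach correction by single-exponential decay
#'
#' Fits \code{I(t) = I0 exp(-t / tau)} by nonlinear least squares to
#' zero-nucleotide (control) band intensities and returns the fitted decay,
#' plus the input series divided by it. Apply the returned \code{decay}
#' function to correct other exposures from the same recording. Flat control
#' series (no detectable bleaching) yield \code{tau = Inf} and an identity
#' correction.
#'
#' @param times exposure times in s (>= 3 control points spanning the
#'   recording).
#' @param intensities band intensities at those times (must be positive).
#' @return list with \code{tau} (s), \code{i0}, \code{decay} (function of t),
#'   and \code{corrected} (= \code{intensities / decay(times)}).
#' @export
bleach_correct <- function(times, intensities) {
  stopifnot(length(times) == length(intensities))
  if (length(times) < 3)
    stop("bleach correction needs >= 3 zero-nucleotide points")
  if (any(intensities <= 0))
    stop("non-positive control intensities; check background subtraction")
  slope <- unname(stats::coef(stats::lm(log(intensities) ~ times))[2])
  if (abs(slope) < 1e-12) {
    decay <- function(t) rep(1, length(t))
    return(list(tau = Inf, i0 = mean(intensities), decay = decay,
                corrected = intensities))
  }
  tau0 <- -1 / slope
  if (tau0 <= 0)
    stop("fitted bleach time constant is non-positive (tau ~ ", signif(tau0, 3),
         " s): control intensities increase over time")
  df <- data.frame(t = times, I = intensities)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ i0 * exp(-t / tau), data = df,
                      start = list(i0 = unname(intensities[1]), tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("bleach fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["tau"]] <= 0)
    stop("fitted bleach time constant is non-positive (tau = ",
         signif(cf[["tau"]], 3), " s)")
  tau <- cf[["tau"]]; i0 <- cf[["i0"]]
  decay <- function(t) exp(-t / tau)
  list(tau = tau, i0 = i0, decay = decay,
       corrected = intensities / decay(times))
}

# mean of the steady-state window: the final `frac` of a segment's samples
segment_mean <- function(samples, frac = 0.5) {
  n <- length(samples)
  mean(samples[seq.int(max(1L, n - ceiling(frac * n) + 1L), n)])
}

#' Zero-current offset from a barium application
#'
#' KATP currents are fully blocked by Ba2+, so the plateau current of the
#' barium segment estimates the true zero-current level; subtract it from all
#' segments. The plateau is summarised as the mean of the final half of the
#' segment.
#'
#' @param samples current samples (pA) of the Ba2+ application.
#' @return baseline offset (pA).
#' @export
zero_current_offset <- function(samples) {
  if (!length(samples)) stop("empty barium segment")
  segment_mean(samples)
}

#' Rundown-corrected fractional current
#'
#' The test-segment current expressed as a fraction of the bracketing
#' nucleotide-free controls:
#' \code{mean(test) / mean(c(mean(pre), mean(post)))}. Bracketing cancels
#' slow multiplicative rundown to first order. Segment currents are
#' summarised as the mean of the final half of each segment (steady state);
#' all inputs are assumed already offset-corrected. Fractions above 1 are
#' preserved, not clipped.
#'
#' @param pre,test,post current samples (pA) of the preceding control, the
#'   test application and the following control.
#' @return fractional current (scalar).
#' @export
fractional_current <- function(pre, test, post) {
  mp <- segment_mean(pre); mt <- segment_mean(test); ms <- segment_mean(post)
  if (mp <= 0 || ms <= 0)
    stop("non-positive control current (pre = ", signif(mp, 3), ", post = ",
         signif(ms, 3), " pA): patch unusable")
  mt / mean(c(mp, ms))
}

#' Reduce patch recordings to a tidy dose-response table
#'
#' Applies the full correction chain per patch: zero-current offset from the
#' barium segment (when present; otherwise 0 with a warning), steady-state
#' segment means, bracketed rundown correction of each test application, and
#' -- when spectra are present -- background subtraction, ANAP-band
#' quantification (with optional GFP-crosstalk subtraction), single-exponential
#' bleach correction fitted on the zero-nucleotide exposures, and fractional
#' quenching referenced to the nearest-in-time corrected control exposure.
#'
#' @param recordings a list of patch recordings as produced by
#'   \code{\link{gen_pcf_dataset}} (see its documentation for the structure).
#' @param band ANAP integration band in nm.
#' @param crosstalk_coef fraction of the 505-515 nm (GFP) band intensity
#'   subtracted from the ANAP band (default 0: off).
#' @param gfp_band GFP band used for the crosstalk estimate.
#' @return data.frame with one row per test application: \code{patch},
#'   \code{construct}, \code{conc}, \code{frac_current} and
#'   \code{frac_quench} (all NA when the patch has no spectra, in which case
#'   the column is dropped if no patch has spectra).
#' @export
build_dose_response <- function(recordings, band = c(469.5, 474.5),
                                crosstalk_coef = 0, gfp_band = c(505, 515)) {
  if (inherits(recordings, "patch_recording")) recordings <- list(recordings)
  rows <- list()
  for (rec in recordings) {
    apps <- rec$applications
    has_spec <- !is.null(rec$spectra) && any(!vapply(rec$spectra, is.null,
                                                     logical(1)))
    ba <- which(apps$solution == "barium")
    offset <- if (length(ba)) zero_current_offset(rec$currents[[ba[1]]]) else {
      # a Ba2+ zero-current reference is only required when quenching
      # (spectral) data are analysed
      if (has_spec)
        warning("patch ", rec$patch_id,
                ": no barium segment; zero-current offset set to 0")
      0
    }
    seg <- vapply(rec$currents, segment_mean, numeric(1)) - offset
    if (has_spec) {
      bandi <- rep(NA_real_, nrow(apps))
      spec_t <- rep(NA_real_, nrow(apps))
      for (i in seq_len(nrow(apps))) {
        sp <- rec$spectra[[i]]
        if (is.null(sp)) next
        cor <- subtract_background(sp, rec$background)
        v <- anap_band_intensity(cor, band)
        if (crosstalk_coef != 0)
          v <- v - crosstalk_coef * anap_band_intensity(cor, gfp_band)
        bandi[i] <- v
        spec_t[i] <- sp$time
      }
      ctrl <- which(apps$solution == "control" & !is.na(bandi))
      bl <- bleach_correct(spec_t[ctrl], bandi[ctrl])
      corrected <- bandi / bl$decay(spec_t)
    }
    test_idx <- which(apps$solution == "test")
    ctrl_idx <- which(apps$solution == "control")
    for (k in test_idx) {
      pre <- max(ctrl_idx[ctrl_idx < k])
      post_c <- ctrl_idx[ctrl_idx > k]
      if (!is.finite(pre) || !length(post_c)) next
      post <- min(post_c)
      fc <- fractional_current(rec$currents[[pre]] - offset,
                               rec$currents[[k]] - offset,
                               rec$currents[[post]] - offset)
      fq <- NA_real_
      if (has_spec && !is.na(corrected[k])) {
        ctrl_with_spec <- ctrl_idx[!is.na(corrected[ctrl_idx])]
        nearest <- ctrl_with_spec[which.min(abs(spec_t[ctrl_with_spec] -
                                                  spec_t[k]))]
        fq <- 1 - corrected[k] / corrected[nearest]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patch = rec$patch_id, construct = rec$construct,
        conc = apps$conc[k], frac_current = fc, frac_quench = fq)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(is.na(out$frac_quench))) out$frac_quench <- NULL
  out
}
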