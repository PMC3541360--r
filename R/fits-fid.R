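# Fluorescent intercalator displacement (FID): trapezium-rule emission
# areas, % thiazole-orange displacement, and 4PL midpoint (DC50/EC50)
# fitting shared with luciferase dose-response curves.

#' Trapezium-rule area of an emission spectrum
#'
#' Composite trapezoidal integral of intensity over [lo, hi] nm, with
#' linear interpolation at the window edges when they fall between
#' sampled wavelengths. Exact for piecewise-linear spectra.
#'
#' @param wavelength increasing wavelengths, nm.
#' @param intensity intensities.
#' @param lo,hi integration window, defaults 510 and 750 nm (thiazole
#'   orange emission window).
#' @return the area (intensity x nm).
#' @export
trapeziumArea <- function(wavelength, intensity, lo = 510, hi = 750) {
  stopifnot(length(wavelength) == length(intensity))
  if (any(diff(wavelength) <= 0)) stop("wavelengths must be increasing")
  if (lo < min(wavelength) || hi > max(wavelength))
    stop("integration window [", lo, ", ", hi, "] outside data range")
  if (lo >= hi) stop("lo must be < hi")
  inside <- wavelength > lo & wavelength < hi
  x <- c(lo, wavelength[inside], hi)
  y <- c(stats::approx(wavelength, intensity, xout = lo)$y,
         intensity[inside],
         stats::approx(wavelength, intensity, xout = hi)$y)
  pracma::trapz(x, y)
}

#' Percent thiazole-orange displacement
#'
#' 100 - (sample area / standard area * 100), the standard being the
#' G4 + TO spectrum without ligand. Negative values (sample brighter than
#' the standard) are returned as-is with a warning.
#'
#' @param areaSample fluorescence area with ligand.
#' @param areaStandard fluorescence area without ligand (> 0).
#' @return percent displacement.
#' @export
toDisplacement <- function(areaSample, areaStandard) {
  if (any(areaStandard <= 0)) stop("standard area must be > 0")
  out <- 100 - (areaSample / areaStandard) * 100
  if (any(out < 0))
    warning("negative displacement: sample area exceeds the standard")
  out
}

.fourPL <- function(x, bottom, top, logMid, hill) {
  bottom + (top - bottom) / (1 + 10^((logMid - log10(x)) * hill))
}

#' Fit a four-parameter-logistic midpoint (DC50 / EC50)
#'
#' Fits response = bottom + (top-bottom) / (1 + 10^((logMid - logX)*hill))
#' on log10 concentration with deterministic multi-starts and a Hill
#' slope bounded in [0.2, 5]. The midpoint is the concentration at
#' (top+bottom)/2. When the fitted plateaus are not bracketed by the data
#' the fit falls back to monotone linear interpolation of the response at
#' the 50% level (between the observed extremes), flagged in `@method`.
#'
#' @param concentration positive concentrations (conventionally uM).
#' @param response responses (e.g. % TO displacement, or luciferase
#'   ratio).
#' @param kind "DC50" (displacement) or "EC50" (activation); label only.
#' @param noiseTol monotonicity tolerance, as a fraction of the response
#'   range, beyond which non-monotone data are rejected.
#' @return a [SigmoidFit-class].
#' @export
fitMidpoint <- function(concentration, response, kind = c("DC50", "EC50"),
                        noiseTol = 0.2) {
  kind <- match.arg(kind)
  stopifnot(length(concentration) == length(response))
  if (length(concentration) < 5L)
    stop("need at least 5 concentrations spanning the transition")
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  ord <- order(concentration)
  x <- concentration[ord]; y <- response[ord]
  rng <- diff(range(y))
  if (rng == 0) stop("flat response: no transition to fit")
  # reject gross non-monotonicity (beyond noise)
  runMax <- cummax(y); runMin <- cummin(y)
  up <- max(runMax - y); down <- max(y - runMin)
  if (min(up, down) > noiseTol * rng)
    stop("response is not monotone beyond the noise tolerance")

  increasing <- stats::cor(log10(x), y) >= 0
  b0 <- if (increasing) min(y) else max(y)
  t0 <- if (increasing) max(y) else min(y)
  midGrid <- stats::quantile(log10(x), probs = seq(0.2, 0.8, length.out = 4))
  best <- NULL
  for (m0 in midGrid) for (h0 in c(0.7, 1.5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .fourPL(x, bottom, top, logMid, hill),
        start = list(bottom = b0, top = t0, logMid = m0, hill = h0),
        lower = c(bottom = -Inf, top = -Inf,
                  logMid = log10(min(x)) - 2, hill = 0.2),
        upper = c(bottom = Inf, top = Inf,
                  logMid = log10(max(x)) + 2, hill = 5),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }

  if (!is.null(best)) {
    cf <- coef(best$fit)
    mid <- 10^cf[["logMid"]]
    # plateaus must be bracketed by the sampled concentrations for the
    # midpoint to be an interpolation rather than an extrapolation
    bracketed <- mid >= min(x) && mid <= max(x)
    if (bracketed) {
      se <- tryCatch(sqrt(diag(vcov(best$fit))),
                     error = function(e) setNames(rep(NA_real_, 4), names(cf)))
      seMid <- if (is.na(se[["logMid"]])) NA_real_ else
        abs(mid * log(10) * se[["logMid"]])
      return(methods::new("SigmoidFit",
          midpoint = mid, hill = cf[["hill"]],
          top = cf[["top"]], bottom = cf[["bottom"]], kind = kind,
          se = c(midpoint = seMid, hill = unname(se["hill"]),
                 top = unname(se["top"]), bottom = unname(se["bottom"])),
          method = "4PL"))
    }
  }
  # fallback: monotone interpolation at the 50% response level
  warning("plateaus not bracketed by the data; ",
          "falling back to linear interpolation at the 50% level")
  half <- (min(y) + max(y)) / 2
  ys <- if (increasing) y else rev(y)
  xs <- if (increasing) x else rev(x)
  mid <- stats::approx(ys, xs, xout = half, ties = "ordered")$y
  if (is.na(mid)) stop("could not interpolate the 50% response level")
  methods::new("SigmoidFit",
      midpoint = mid, hill = NA_real_, top = max(y), bottom = min(y),
      kind = kind, se = c(midpoint = NA_real_), method = "interpolation")
}

#' FID displacement table from emission spectra
#'
#' Computes trapezium-rule areas for a list of ligand-titration spectra
#' and the no-ligand standard, converts them to % TO displacement, and
#' optionally fits the DC50.
#'
#' @param spectra named list of data.frames with columns `wavelength_nm`,
#'   `intensity`; names are the ligand concentrations in uM.
#' @param standard data.frame for the no-ligand standard spectrum.
#' @param lo,hi integration window, nm.
#' @param fit fit a DC50 through [fitMidpoint()]?
#' @return list with `table` (conc_uM, area, displacement_pct) and `fit`
#'   (a [SigmoidFit-class] or NULL).
#' @export
fidAnalysis <- function(spectra, standard, lo = 510, hi = 750, fit = TRUE) {
  a0 <- trapeziumArea(standard$wavelength_nm, standard$intensity, lo, hi)
  conc <- as.numeric(names(spectra))
  if (anyNA(conc)) stop("spectra must be named by concentration (uM)")
  areas <- vapply(spectra, function(s)
    trapeziumArea(s$wavelength_nm, s$intensity, lo, hi), numeric(1))
  disp <- toDisplacement(areas, a0)
  tab <- data.frame(conc_uM = conc, area = areas,
                    displacement_pct = disp)
  tab <- tab[order(tab$conc_uM), , drop = FALSE]
  sf <- if (fit) fitMidpoint(tab$conc_uM, tab$displacement_pct, "DC50")
        else NULL
  list(table = tab, fit = sf)
}
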