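test_that("two-state melting fit recovers noiseless truth to 4 significant figures", {
  curve <- simulateMeltingCurve(tm = 71.4, dH = 170, noise = 0)
  fit <- fitMeltingTwoState(curve$temperature_C, curve$signal)
  expect_equal(fit@tm, 71.4, tolerance = 1e-4)
  expect_equal(fit@dH, 170, tolerance = 1e-4)
  # two-state identities: dS = 1000*dH/Tm(K) and dG(Tm) = 0
  expect_equal(fit@dS, 1000 * fit@dH / (fit@tm + 273.15), tolerance = 1e-10)
  expect_equal(meltingDG(fit, fit@tm + 273.15), 0, tolerance = 1e-8)
  # forward-simulate -> fit -> forward-simulate reproduces the curve
  refit <- simulateMeltingCurve(tm = fit@tm, dH = fit@dH,
                                baselines = fit@baselines, noise = 0)
  expect_equal(refit$signal, curve$signal, tolerance = 1e-6)
  expect_error(fitMeltingTwoState(1:5, 1:5), "12 points")
})

test_that("dG at body temperature follows dH - T*dS", {
  # closed form on the printed-precision parameter pair
  expect_equal(170 - 310 * 494 / 1000, 16.86, tolerance = 1e-12)
  curve <- simulateMeltingCurve(tm = 71.4, dH = 170, noise = 0)
  fit <- fitMeltingTwoState(curve$temperature_C, curve$signal)
  expect_equal(meltingDG(fit, 310), fit@dH - 310 * fit@dS / 1000,
               tolerance = 1e-12)
  expect_equal(meltingDG(fit, 310), 17.04, tolerance = 0.01)
})

test_that("melting parameters are unbiased at 1% noise", {
  tms <- numeric(100); dhs <- numeric(100)
  for (s in 1:100) {
    curve <- simulateMeltingCurve(tm = 71.4, dH = 170, noise = 0.01,
                                  seed = s)
    fit <- fitMeltingTwoState(curve$temperature_C, curve$signal)
    tms[s] <- fit@tm; dhs[s] <- fit@dH
  }
  expect_lt(abs(mean(tms) - 71.4), 0.3)
  expect_lt(abs(mean(dhs) - 170) / 170, 0.05)
})

test_that("double-exponential fit recovers noiseless truth and orders the rates", {
  tr <- simulateKineticTrace(A1 = 0.5, k1 = 1e-2, A2 = 0.5, k2 = 3e-4,
                             C = 0, noise = 0)
  fit <- fitDoubleExponential(tr$time_s, tr$signal)
  expect_identical(fit@model, "double")
  expect_gte(fit@k1, fit@k2)
  expect_equal(fit@k1, 1e-2, tolerance = 1e-6)
  expect_equal(fit@k2, 3e-4, tolerance = 1e-6)
  expect_equal(fit@A1, 0.5, tolerance = 1e-6)
  expect_equal(fit@A2, 0.5, tolerance = 1e-6)
  expect_equal(fit@C0, 0, tolerance = 1e-8)
  expect_error(fitDoubleExponential(c(0, 1, 1.5), c(1, 2, 3)), "20 points")
})

test_that("a pure single exponential selects the single-exponential model", {
  tr <- simulateKineticTrace(A1 = 1, k1 = 2e-3, A2 = 0, k2 = 1e-3, C = 0.1,
                             noise = 0.002, seed = 3)
  fit <- fitDoubleExponential(tr$time_s, tr$signal)
  expect_identical(fit@model, "single")
  expect_equal(fit@k1, 2e-3, tolerance = 0.05)
  expect_identical(fit@A2, 0)
})

test_that("kinetic rates are unbiased at 2% noise", {
  k1s <- numeric(100); k2s <- numeric(100)
  for (s in 1:100) {
    tr <- simulateKineticTrace(noise = 0.02, seed = 200 + s)
    fit <- fitDoubleExponential(tr$time_s, tr$signal)
    k1s[s] <- fit@k1; k2s[s] <- if (fit@model == "double") fit@k2 else NA
  }
  expect_lt(abs(mean(k1s, na.rm = TRUE) - 1e-2) / 1e-2, 0.05)
  expect_lt(abs(mean(k2s, na.rm = TRUE) - 3e-4) / 3e-4, 0.05)
})

test_that("kinetic fits are equivariant to amplitude and time-unit rescaling", {
  tr <- simulateKineticTrace(noise = 0)
  f0 <- fitDoubleExponential(tr$time_s, tr$signal)
  f1 <- fitDoubleExponential(tr$time_s, 7 * tr$signal)
  expect_equal(f1@k1, f0@k1, tolerance = 1e-6)
  expect_equal(f1@A1, 7 * f0@A1, tolerance = 1e-5)
  # time in minutes: rates scale by 60
  f2 <- fitDoubleExponential(tr$time_s / 60, tr$signal)
  expect_equal(f2@k1, 60 * f0@k1, tolerance = 1e-5)
  expect_equal(f2@k2, 60 * f0@k2, tolerance = 1e-5)
})

test_that("pseudo-first-order normalisation is a checked division", {
  expect_equal(pseudoFirstOrder(8e-3, 2e-6), 4e3)
  expect_equal(pseudoFirstOrder(0, 2e-6), 0)
  expect_equal(pseudoFirstOrder(8e-3, 4e-6), 2e3)
  expect_error(pseudoFirstOrder(1e-3, 0), "> 0")
})

test_that("Arrhenius fit recovers the activation energy", {
  rates <- simulateRates(Ea = 22.1, temperature = c(25, 35, 45, 55))
  fit <- fitArrhenius(rates$temperature_C, rates$k, celsius = TRUE)
  expect_equal(fit@Ea, 22.1, tolerance = 1e-6)
  # temperature-independent rates -> Ea = 0
  flat <- fitArrhenius(c(298, 308, 318), rep(1e-3, 3))
  expect_equal(flat@Ea, 0, tolerance = 1e-12)
  expect_error(fitArrhenius(c(298, 308), c(1e-3, 2e-3)), "3 temperatures")
  expect_error(fitArrhenius(c(298, 308, 318), c(1e-3, -1, 2e-3)), "positive")
  # 5% lognormal noise: small bias over replicates
  eas <- vapply(1:100, function(s) {
    r <- simulateRates(Ea = 22.1, noise = 0.05, seed = s)
    fitArrhenius(r$temperature_C, r$k, celsius = TRUE)@Ea
  }, numeric(1))
  expect_lt(abs(mean(eas) - 22.1) / 22.1, 0.05)
})

test_that("Eyring conversion and fit agree with the Arrhenius route", {
  # the printed activation energy converts to the printed enthalpy
  eyr <- eyringParams(Ea = 22.1, Tref = 298.15)
  expect_equal(round(eyr@dH_act, 1), 19.6)
  # rate-based route on synthetic rates from known (dH, dS)
  TK <- c(298.15, 308.15, 318.15, 328.15)
  dH <- 19.6e3; dS <- -249.2
  k <- (1.380649e-23 * TK / 6.62607015e-34) *
    exp(-dH / (8.314 * TK)) * exp(dS / 8.314)
  fit <- eyringParams(TK, k)
  expect_equal(fit@dH_act, 19.6, tolerance = 1e-6)
  expect_equal(fit@dS_act, -249.2, tolerance = 1e-4)
  # consistency: dH_act = Ea - R*T_mean within 2%
  arr <- fitArrhenius(TK, k)
  expect_equal(fit@dH_act, arr@Ea - 8.314 * mean(TK) / 1000,
               tolerance = 0.02 * fit@dH_act)
})

test_that("trapezium areas are exact for piecewise-linear spectra", {
  # constant intensity 1 over the default window
  wl <- seq(500, 760, by = 5)
  expect_equal(trapeziumArea(wl, rep(1, length(wl))), 240)
  # triangle peak: area = base * height / 2
  wlT <- c(500, 600, 640, 680, 760)
  intT <- c(0, 0, 2, 0, 0)
  expect_equal(trapeziumArea(wlT, intT, 510, 750), 80)
  # edge interpolation: window borders inside a linear ramp
  wlR <- c(500, 760); intR <- c(0, 26)
  ramp <- function(x) 26 * (x - 500) / 260
  expect_equal(trapeziumArea(wlR, intR, 510, 750),
               (ramp(510) + ramp(750)) / 2 * 240)
  expect_error(trapeziumArea(wlT, intT, 400, 750), "outside")
  expect_error(trapeziumArea(c(1, 1, 2), c(0, 0, 0)), "increasing")
  # refinement oracle on a smooth spectrum
  f <- function(x) exp(-(x - 560)^2 / 800) + 0.3 * exp(-(x - 650)^2 / 5000)
  coarse <- seq(510, 750, by = 6)
  fine <- seq(510, 750, by = 0.02)
  riemann <- sum(f(head(fine, -1))) * 0.02
  expect_equal(trapeziumArea(coarse, f(coarse)) / riemann, 1,
               tolerance = 1e-3)
})

test_that("percent TO displacement follows the FID formula", {
  expect_equal(toDisplacement(10, 10), 0)
  expect_equal(toDisplacement(0, 10), 100)
  expect_equal(toDisplacement(5, 10), 50)
  expect_warning(d <- toDisplacement(12, 10), "negative")
  expect_equal(d, -20)
  expect_error(toDisplacement(1, 0), "> 0")
})

test_that("4PL midpoint fit is exact on noiseless data and scale-equivariant", {
  d <- simulateDoseResponse(midpoint = 0.31, hill = 1.5, noise = 0)
  fit <- fitMidpoint(d$conc_uM, d$response, "DC50")
  expect_identical(fit@method, "4PL")
  expect_equal(fit@midpoint, 0.31, tolerance = 1e-6)
  expect_equal(fit@hill, 1.5, tolerance = 1e-6)
  # response at the midpoint is the plateau average
  mid <- fit@midpoint
  predMid <- fit@bottom + (fit@top - fit@bottom) /
    (1 + 10^((log10(mid) - log10(mid)) * fit@hill))
  expect_equal(predMid, (fit@top + fit@bottom) / 2)
  # concentration rescaling scales the midpoint
  f2 <- fitMidpoint(3 * d$conc_uM, d$response, "DC50")
  expect_equal(f2@midpoint, 3 * fit@midpoint, tolerance = 1e-5)
  expect_error(fitMidpoint(c(1, 2, 5, 10, 20), rep(0, 5)), "flat")
})

test_that("DC50 is recovered within 10% at 2% noise over 50 seeds", {
  mids <- vapply(1:50, function(s) {
    d <- simulateDoseResponse(midpoint = 0.31, hill = 1.5, noise = 2,
                              seed = 40 + s)
    fitMidpoint(d$conc_uM, d$response, "DC50")@midpoint
  }, numeric(1))
  expect_lt(abs(mean(mids) - 0.31) / 0.31, 0.10)
})

test_that("FID spectra analysis reproduces the planted displacement curve", {
  conc <- c(0.125, 0.25, 0.5, 1, 2, 5)
  truthDisp <- 100 / (1 + (0.31 / conc)^1.5)
  spectra <- lapply(truthDisp, function(d)
    simulateEmissionSpectrum(scale = (100 - d) / 100))
  names(spectra) <- conc
  std <- simulateEmissionSpectrum(scale = 1)
  out <- fidAnalysis(spectra, std)
  expect_equal(out$table$displacement_pct, truthDisp, tolerance = 1e-6)
  expect_equal(out$fit@midpoint, 0.31, tolerance = 0.02)
})
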