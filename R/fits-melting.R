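# Two-state van't Hoff melting model with linear folded/unfolded
# baselines:
#   signal(T) = [ (bf0 + bf1*T) + (bu0 + bu1*T) * K(T) ] / (1 + K(T))
#   K(T) = exp[ (dH/R) * (1/Tm - 1/T) ]
# dH in J/mol, T and Tm in K. At T = Tm, K = 1 and the unfolded fraction
# is 1/2; dS = dH/Tm follows from dG(Tm) = 0.

.meltModel <- function(T, Tm, dH, bf0, bf1, bu0, bu1) {
  K <- exp((dH / .R_GAS) * (1 / Tm - 1 / T))
  ((bf0 + bf1 * T) + (bu0 + bu1 * T) * K) / (1 + K)
}

#' Fit a two-state van't Hoff melting curve
#'
#' Least-squares fit of a folded/unfolded two-state equilibrium with
#' linear baselines to a (temperature, signal) melting curve, as used for
#' CD melting of G-quadruplexes. Unfolding entropy is derived from the
#' two-state constraint dS = dH/Tm (so dG(Tm) = 0 identically), and free
#' energy at any query temperature as dG(T) = dH - T*dS.
#'
#' @param temperature numeric vector, in Kelvin unless `celsius = TRUE`.
#' @param signal numeric vector (CD signal, any units).
#' @param celsius interpret `temperature` as degrees C (default TRUE,
#'   matching instrument exports).
#' @param nStarts number of deterministic multi-starts over the dH grid.
#' @return a [MeltingFit-class].
#' @export
fitMeltingTwoState <- function(temperature, signal, celsius = TRUE,
                               nStarts = 8L) {
  stopifnot(length(temperature) == length(signal))
  if (length(temperature) < 12L)
    stop("need at least 12 points spanning baselines and transition")
  TK <- if (celsius) temperature + 273.15 else temperature
  ord <- order(TK); TK <- TK[ord]; y <- signal[ord]

  # baseline starts from the outer 25% of points; Tm start from the
  # steepest part of a smoothed derivative
  nEdge <- max(3L, floor(length(TK) / 4))
  lo <- stats::lm(y ~ TK, data = data.frame(TK = head(TK, nEdge),
                                            y = head(y, nEdge)))
  hi <- stats::lm(y ~ TK, data = data.frame(TK = tail(TK, nEdge),
                                            y = tail(y, nEdge)))
  dmid <- diff(y) / diff(TK)
  tmGuess <- TK[which.max(abs(dmid))]
  dHGrid <- seq(80e3, 500e3, length.out = nStarts)

  best <- NULL
  for (dH0 in dHGrid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .meltModel(TK, Tm, dH, bf0, bf1, bu0, bu1),
        start = list(Tm = tmGuess, dH = dH0,
                     bf0 = unname(coef(lo)[1]), bf1 = unname(coef(lo)[2]),
                     bu0 = unname(coef(hi)[1]), bu1 = unname(coef(hi)[2])),
        lower = c(Tm = min(TK), dH = 1e3,
                  bf0 = -Inf, bf1 = -Inf, bu0 = -Inf, bu1 = -Inf),
        upper = c(Tm = max(TK), dH = 2e6,
                  bf0 = Inf, bf1 = Inf, bu0 = Inf, bu1 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("two-state melting fit failed to converge from all starts")
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    setNames(rep(NA_real_, length(cf)), names(cf)))
  TmK <- cf[["Tm"]]
  if (TmK <= min(TK) + 1e-6 || TmK >= max(TK) - 1e-6)
    warning("fitted transition lies at the edge of the data range")
  dH_kJ <- cf[["dH"]] / 1000
  dS <- cf[["dH"]] / TmK               # J/mol/K
  methods::new("MeltingFit",
      tm = TmK - 273.15,
      dH = dH_kJ,
      dS = dS,
      baselines = c(bf0 = cf[["bf0"]], bf1 = cf[["bf1"]],
                    bu0 = cf[["bu0"]], bu1 = cf[["bu1"]]),
      se = c(Tm = unname(se["Tm"]), dH = unname(se["dH"]) / 1000),
      data = data.frame(temperature_K = TK, signal = y),
      converged = TRUE)
}

#' Free energy of unfolding at a query temperature
#'
#' dG(T) = dH - T*dS from the fitted (unrounded) parameters, in kJ/mol.
#' dG(Tm) = 0 by construction of the two-state fit.
#'
#' @param fit a [MeltingFit-class].
#' @param T_K query temperature in Kelvin (default 310 K, body
#'   temperature, the convention for promoter-G4 stability tables).
#' @return dG in kJ mol-1.
#' @export
meltingDG <- function(fit, T_K = 310) {
  stopifnot(methods::is(fit, "MeltingFit"))
  fit@dH - T_K * fit@dS / 1000
}
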