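## Ionic-strength-dependent electrostatic binding model and its fits.
## Concentrations are in M here; the gas constant is fixed at
## 8.314 J K^-1 mol^-1 and the standard state for Kd <-> Delta-G is 1 M.

GAS_CONSTANT <- 8.314  # J K^-1 mol^-1

screeningFactor <- function(c1, ionicStrength) {
  s <- sqrt(ionicStrength)
  exp(-c1 * s) / (1 + c1 * s)
}

#' Screened electrostatic binding free energy
#'
#' Semi-empirical Debye-Hueckel-type model for the total standard binding
#' free energy as a function of ionic strength:
#' `dG(I) = dgNio + dgIo0 * exp(-c1*sqrt(I)) / (1 + c1*sqrt(I))`.
#' At `I = 0` the screening factor is 1 (full electrostatic contribution);
#' at high `I` only the non-ionic component `dgNio` remains.
#'
#' @param ionicStrength ionic strength (M), `>= 0`; vectorised.
#' @param params an [IonicBindingParams-class].
#' @return binding free energy (J/mol).
#' @examples
#' p <- ionicBindingParams(-20400, -28900, 1.53)
#' bindingFreeEnergy(0.2, p) / 1000  # ~ -29 kJ/mol
#' @export
bindingFreeEnergy <- function(ionicStrength, params) {
  stopifnot(is(params, "IonicBindingParams"))
  if (any(!is.finite(ionicStrength)) || any(ionicStrength < 0)) {
    stop("'ionicStrength' must be >= 0")
  }
  params@dgNio + params@dgIo0 * screeningFactor(params@c1, ionicStrength)
}

#' @rdname bindingFreeEnergy
#' @param dgNio non-ionic binding free energy (J/mol).
#' @param dgIo0 electrostatic binding free energy at I = 0 (J/mol).
#' @param c1 screening parameter (M^-1/2).
#' @param temperature absolute temperature (K).
#' @param rss residual sum of squares (J^2/mol^2) when fitted.
#' @export
ionicBindingParams <- function(dgNio, dgIo0, c1, temperature = 293,
                               rss = NA_real_) {
  new("IonicBindingParams", dgNio = dgNio, dgIo0 = dgIo0, c1 = c1,
      temperature = temperature, rss = rss)
}

setMethod("show", "IonicBindingParams", function(object) {
  cat("IonicBindingParams (screened electrostatic binding):\n")
  cat(sprintf("  dgNio = %.5g J/mol, dgIo0 = %.5g J/mol, c1 = %.4g M^-1/2\n",
              object@dgNio, object@dgIo0, object@c1))
  cat(sprintf("  T = %g K%s\n", object@temperature,
              if (is.finite(object@rss)) {
                sprintf(", rss(dG) = %.4g", object@rss)
              } else ""))
})

#' Convert between dissociation constant and standard binding free energy
#'
#' `kd = exp(dg / (R*T))` with 1 M standard state; the inverse is
#' `dg = R*T*log(kd)`.
#'
#' @param dg standard binding free energy (J/mol).
#' @param kd dissociation constant (M), `> 0`.
#' @param temperature absolute temperature (K), `> 0`.
#' @return `kdFromDg()` a Kd in M; `dgFromKd()` a free energy in J/mol.
#' @examples
#' dgFromKd(6.7e-6, 293)  # ~ -2.90e4 J/mol
#' @export
kdFromDg <- function(dg, temperature = 293) {
  if (temperature <= 0) stop("'temperature' must be > 0")
  exp(dg / (GAS_CONSTANT * temperature))
}

#' @rdname kdFromDg
#' @export
dgFromKd <- function(kd, temperature = 293) {
  if (temperature <= 0) stop("'temperature' must be > 0")
  if (any(kd <= 0)) stop("'kd' must be > 0")
  GAS_CONSTANT * temperature * log(kd)
}

# Profile out the two free energies, which enter linearly once c1 is fixed:
# dG_i = dgNio + dgIo0 * s_i(c1). Returns the linear solve and its rss.
ionicLinearFit <- function(c1, ionicStrength, dg) {
  s <- screeningFactor(c1, ionicStrength)
  X <- cbind(1, s)
  beta <- qr.solve(X, dg)
  r <- dg - X %*% beta
  list(dgNio = unname(beta[1]), dgIo0 = unname(beta[2]), rss = sum(r^2))
}

#' Fit the screened electrostatic binding model to (I, Kd) data
#'
#' Converts each dissociation constant to a binding free energy
#' (`dgFromKd()`) and least-squares fits [bindingFreeEnergy()] in Delta-G
#' (log-Kd) space, which equalises the large dynamic range of the Kd values.
#' The two free energies enter linearly for fixed `c1`, so the fit profiles
#' them out and searches `c1` deterministically: a documented multi-start
#' grid `c1 in {0.5, 1, 1.5, 2, 3}`, golden-section refinement around the
#' best start, and a final linear solve. With exactly three distinct points
#' the fit interpolates.
#'
#' @param ionicStrength ionic strengths (M), at least 3 distinct values.
#' @param kd dissociation constants (M), same length.
#' @param temperature absolute temperature (K).
#' @return an [IonicBindingParams-class] with the fitted `rss` (in Delta-G
#'   space).
#' @examples
#' fitIonic(c(0.2, 0.8, 2.1), c(6.7e-6, 65e-6, 155e-6), 293)
#' @export
fitIonic <- function(ionicStrength, kd, temperature = 293) {
  if (length(ionicStrength) != length(kd)) {
    stop("'ionicStrength' and 'kd' must have the same length")
  }
  if (length(kd) < 3L) {
    stop("under-determined: need at least 3 (I, Kd) points")
  }
  if (anyDuplicated(ionicStrength)) {
    stop("degenerate input: ionic strengths must be distinct")
  }
  if (any(ionicStrength <= 0) || any(kd <= 0)) {
    stop("'ionicStrength' and 'kd' must be > 0")
  }
  dg <- dgFromKd(kd, temperature)
  starts <- c(0.5, 1, 1.5, 2, 3)
  rssStart <- vapply(starts,
                     function(c1) ionicLinearFit(c1, ionicStrength, dg)$rss,
                     numeric(1))
  best <- starts[which.min(rssStart)]
  opt <- stats::optimize(
    function(c1) ionicLinearFit(c1, ionicStrength, dg)$rss,
    interval = c(best / 8, best * 8), tol = 1e-10)
  fin <- ionicLinearFit(opt$minimum, ionicStrength, dg)
  ionicBindingParams(fin$dgNio, fin$dgIo0, opt$minimum,
                     temperature = temperature, rss = fin$rss)
}

#' @rdname deffOfCharge
#' @param dgNio non-ionic binding free energy (J/mol).
#' @param dgPc electrostatic binding free energy per unit net charge
#'   (J mol^-1 charge^-1).
#' @param c1 screening parameter (M^-1/2).
#' @param rss residual sum of squares on log10(dEff) when fitted.
#' @param boundary logical boundary-solution flag.
#' @export
chargeModelParams <- function(dgNio, dgPc, c1, constants = chargeModelConstants(),
                              rss = NA_real_, boundary = FALSE) {
  new("ChargeModelParams", dgNio = dgNio, dgPc = dgPc, c1 = c1,
      constants = constants, rss = rss, boundary = boundary)
}

#' @rdname deffOfCharge
#' @param dFree free-state diffusion coefficient (um^2/s).
#' @param dBound bound-state (ribosome) diffusion coefficient (um^2/s).
#' @param siteConc binding-site concentration (M; note the unit change from
#'   the uM used in the binding algebra).
#' @param ionicStrength ionic strength (M).
#' @param temperature absolute temperature (K).
#' @export
chargeModelConstants <- function(dFree = 10, dBound = 0.04,
                                 siteConc = 660e-6, ionicStrength = 0.2,
                                 temperature = 293) {
  list(dFree = dFree, dBound = dBound, siteConc = siteConc,
       ionicStrength = ionicStrength, temperature = temperature)
}

setMethod("show", "ChargeModelParams", function(object) {
  cat("ChargeModelParams (charge -> effective diffusion):\n")
  cat(sprintf("  dgNio = %.5g J/mol, dgPc = %.5g J/mol/charge, c1 = %.4g\n",
              object@dgNio, object@dgPc, object@c1))
  cst <- object@constants
  cat(sprintf("  constants: dFree = %g, dBound = %g um^2/s, site = %g M, I = %g M, T = %g K\n",
              cst$dFree, cst$dBound, cst$siteConc, cst$ionicStrength,
              cst$temperature))
  if (is.finite(object@rss)) {
    cat(sprintf("  rss(log10 dEff) = %.4g%s\n", object@rss,
                if (object@boundary) " [boundary: no-binding solution]" else ""))
  }
})

#' Effective diffusion coefficient as a function of probe net charge
#'
#' Composite of the two-state diffusion relation, the binding-site saturation
#' equation, the Kd/free-energy conversion and the screened electrostatic
#' model, with the zero-ionic-strength electrostatic energy taken linear in
#' net charge (`dgIo0 = dgPc * charge`):
#' \deqn{D_{eff}(q) = \left(1 - \frac{[site]}{[site] + e^{\Delta G_b(q)/RT}}\right)
#'   (D_{free} - D_{bound}) + D_{bound}}
#' with \eqn{\Delta G_b(q) = \Delta G_{nio} + \Delta G_{pc}\, q\,
#'   e^{-C_1\sqrt I}/(1 + C_1\sqrt I)}.
#'
#' @param charge net charge in elementary charges; vectorised.
#' @param params a [ChargeModelParams-class].
#' @param constants named list of fixed quantities, see
#'   `chargeModelConstants()`.
#' @return effective diffusion coefficient(s) (um^2/s), always inside
#'   `[dBound, dFree]`.
#' @examples
#' p <- chargeModelParams(-20400, -1156, 1.53)
#' deffOfCharge(c(-30, 0, 25), p)
#' @export
deffOfCharge <- function(charge, params) {
  stopifnot(is(params, "ChargeModelParams"))
  validObject(params)
  cst <- params@constants
  w <- screeningFactor(params@c1, cst$ionicStrength)
  dgB <- params@dgNio + params@dgPc * charge * w
  kd <- exp(dgB / (GAS_CONSTANT * cst$temperature))
  fBound <- cst$siteConc / (cst$siteConc + kd)
  (1 - fBound) * (cst$dFree - cst$dBound) + cst$dBound
}

chargeRss <- function(theta, charge, logDeff, constants, c1Fixed = NULL) {
  c1 <- if (is.null(c1Fixed)) theta[3] else c1Fixed
  if (c1 < 0) return(Inf)
  p <- chargeModelParams(theta[1], theta[2], c1, constants)
  pred <- deffOfCharge(charge, p)
  sum((log10(pred) - logDeff)^2)
}

#' Fit the charge/effective-diffusion model
#'
#' Least squares on `log10(dEff)` (the data span the full range between
#' ribosome and free-GFP mobility, so log residuals weight the slow probes
#' fairly). The search is a deterministic multi-start grid over
#' `dgNio in {-30,-20,-10,-5}*1e3`, `dgPc in {-2000,-1000,-500,-200}` and,
#' when free, `c1 in {0.5, 1, 1.5, 2, 3}`, refined with `nlminb`.
#'
#' At a single fixed ionic strength, `dgPc` and `c1` enter only through the
#' product `dgPc * exp(-c1*sqrt(I))/(1+c1*sqrt(I))`, so they are not
#' separately identifiable; pass a fixed `c1` (e.g. the value from
#' [fitIonic()]) to fit the two free energies alone, or provide per-point
#' `ionicStrength` values (data pooled over organisms) to make all three
#' parameters identifiable.
#'
#' @param charge probe net charges (elementary charges), at least 4 points.
#' @param dEff observed effective diffusion coefficients (um^2/s).
#' @param constants fixed quantities (see `chargeModelConstants()`); the
#'   `ionicStrength` element may be a vector with one value per point.
#' @param c1 optional fixed screening parameter; `NULL` fits it.
#' @return a [ChargeModelParams-class] with `rss` and a `boundary` flag set
#'   when the optimum has effectively no binding anywhere (all bound
#'   fractions < 1e-6, e.g. when all `dEff` equal `dFree`).
#' @examples
#' truth <- chargeModelParams(-20400, -1156, 1.53)
#' q <- c(-30, -7, 0, 7, 15, 25)
#' fitChargeModel(q, deffOfCharge(q, truth), c1 = 1.53)
#' @export
fitChargeModel <- function(charge, dEff, constants = chargeModelConstants(),
                           c1 = NULL) {
  if (length(charge) != length(dEff)) {
    stop("'charge' and 'dEff' must have the same length")
  }
  if (length(charge) < 4L) {
    stop("under-determined: need at least 4 (charge, dEff) points")
  }
  if (any(dEff <= 0)) stop("'dEff' must be > 0")
  nI <- length(constants$ionicStrength)
  if (nI > 1L && nI != length(charge)) {
    stop("per-point 'ionicStrength' must match the number of points")
  }
  logDeff <- log10(dEff)
  obj <- function(theta) chargeRss(theta, charge, logDeff, constants,
                                   c1Fixed = c1)
  starts <- expand.grid(dgNio = c(-30, -20, -10, -5) * 1e3,
                        dgPc = c(-2000, -1000, -500, -200),
                        c1 = if (is.null(c1)) c(0.5, 1, 1.5, 2, 3) else 0)
  bestVal <- Inf
  bestFit <- NULL
  for (k in seq_len(nrow(starts))) {
    th0 <- as.numeric(starts[k, if (is.null(c1)) 1:3 else 1:2])
    fit <- suppressWarnings(stats::nlminb(
      th0, obj,
      lower = c(-1e5, -1e5, if (is.null(c1)) 1e-3),
      upper = c(1e5, 1e5, if (is.null(c1)) 50),
      control = list(iter.max = 500, abs.tol = 1e-14, rel.tol = 1e-12)))
    if (fit$objective < bestVal) {
      bestVal <- fit$objective
      bestFit <- fit
    }
  }
  th <- bestFit$par
  c1Hat <- if (is.null(c1)) th[3] else c1
  p <- chargeModelParams(th[1], th[2], c1Hat, constants, rss = bestVal)
  # boundary: the optimum binds nothing anywhere on the data
  w <- screeningFactor(c1Hat, constants$ionicStrength)
  dgB <- th[1] + th[2] * charge * w
  kd <- exp(dgB / (GAS_CONSTANT * constants$temperature))
  fb <- constants$siteConc / (constants$siteConc + kd)
  p@boundary <- all(fb < 1e-6)
  p
}
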