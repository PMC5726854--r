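## Two-state fast-exchange effective-diffusion algebra and the geometric
## ribosome binding-site census. Concentrations are in uM throughout this
## file; conversion to M happens only at the electrostatics boundary.

#' Effective diffusion coefficient of a fast-exchanging two-state probe
#'
#' A probe that exchanges between a free state (`dFree`) and a bound state
#' (`dBound`) much faster than the measurement time diffuses with a single
#' effective coefficient, the time-weighted average
#' `dEff = fFree*dFree + (1-fFree)*dBound`. This follows from convolving the
#' free- and bound-state Gaussian displacement kernels: their variances
#' `2*dFree*fFree*dt` and `2*dBound*(1-fFree)*dt` add.
#'
#' @param fFree fraction of time spent free, in [0, 1].
#' @param dFree free-state diffusion coefficient (um^2/s).
#' @param dBound bound-state diffusion coefficient (um^2/s), `<= dFree`.
#' @return effective diffusion coefficient (um^2/s); vectorised over `fFree`.
#' @examples
#' effectiveDiffusion(0.01004, 10, 0.04)  # ~0.14, a strongly bound probe
#' @seealso [freeFraction()] for the inverse, [twoStateDiffusion()]
#' @export
effectiveDiffusion <- function(fFree, dFree, dBound) {
  if (any(!is.finite(fFree)) || any(fFree < 0) || any(fFree > 1)) {
    stop("'fFree' must be in [0, 1]")
  }
  if (any(dBound > dFree) || any(dBound < 0)) {
    stop("need dFree >= dBound >= 0")
  }
  fFree * dFree + (1 - fFree) * dBound
}

#' Free fraction from an observed effective diffusion coefficient
#'
#' Inverts the two-state relation: `fFree = (dEff - dBound)/(dFree - dBound)`.
#' Measurement noise can push `dEff` outside `[dBound, dFree]`; such values
#' are clamped to [0, 1] and flagged (attribute `"clamped"`), so population
#' histograms can still be processed.
#'
#' @param dEff observed effective diffusion coefficient (um^2/s).
#' @param dFree free-state diffusion coefficient (um^2/s), `> dBound`.
#' @param dBound bound-state diffusion coefficient (um^2/s).
#' @return free fraction in [0, 1] (vectorised over `dEff`), with a logical
#'   attribute `"clamped"` marking out-of-range inputs.
#' @examples
#' f <- freeFraction(1.9, 10, 0.04)
#' 1 - f  # bound fraction ~0.81
#' @export
freeFraction <- function(dEff, dFree, dBound) {
  if (!is.finite(dFree) || !is.finite(dBound) || dFree <= dBound) {
    stop("'dFree' must exceed 'dBound'")
  }
  f <- (dEff - dBound) / (dFree - dBound)
  clamped <- f < 0 | f > 1
  f <- pmin(1, pmax(0, f))
  attr(f, "clamped") <- clamped
  f
}

#' Construct a two-state diffusion quartet
#'
#' @inheritParams effectiveDiffusion
#' @return a [TwoStateDiffusion-class] with `dEff` computed from the other
#'   three fields.
#' @export
twoStateDiffusion <- function(fFree, dFree, dBound) {
  new("TwoStateDiffusion", dFree = dFree, dBound = dBound, fFree = fFree,
      dEff = effectiveDiffusion(fFree, dFree, dBound))
}

setMethod("show", "TwoStateDiffusion", function(object) {
  cat(sprintf(
    "TwoStateDiffusion: dEff = %.4g um^2/s (fFree = %.4g, dFree = %.4g, dBound = %.4g)\n",
    object@dEff, object@fFree, object@dFree, object@dBound))
})

#' Bound fraction at equilibrium from Kd and binding-site concentration
#'
#' `fBound = siteConc / (kd + siteConc)` — valid when binding sites far
#' outnumber the probe, so site occupancy does not deplete the sites.
#'
#' @param kd dissociation constant (uM), `>= 0`.
#' @param siteConc binding-site concentration (uM), `>= 0`; not both zero.
#' @return bound fraction in [0, 1].
#' @examples
#' boundFraction(6.7, 660)  # ~0.99
#' @export
boundFraction <- function(kd, siteConc) {
  if (any(kd < 0) || any(siteConc < 0)) stop("concentrations must be >= 0")
  if (any(kd + siteConc == 0)) stop("'kd' and 'siteConc' cannot both be zero")
  siteConc / (kd + siteConc)
}

#' Dissociation constant from an observed bound fraction
#'
#' Rearranges the saturation relation: `kd = siteConc * (1 - fBound)/fBound`.
#'
#' @param fBound bound fraction, strictly inside (0, 1).
#' @param siteConc binding-site concentration (uM), `> 0`.
#' @return dissociation constant (uM).
#' @examples
#' kdFromBoundFraction(0.99, 660)  # ~6.7 uM
#' @export
kdFromBoundFraction <- function(fBound, siteConc) {
  if (any(fBound <= 0) || any(fBound >= 1)) {
    stop("'fBound' must be strictly inside (0, 1): ",
         "fBound = 0 gives an infinite Kd, fBound = 1 a zero Kd")
  }
  if (any(siteConc <= 0)) stop("'siteConc' must be > 0")
  siteConc * (1 - fBound) / fBound
}

#' Geometric census of probe-sized binding sites on the ribosome surface
#'
#' Estimates how many nonspecific, probe-sized binding sites the RNA-exposed
#' surface of a spherical ribosome offers, and the resulting cytoplasmic
#' binding-site concentration. The census is a published back-of-the-envelope
#' calculation defined on reported-precision intermediates: the sphere area is
#' rounded to 3 significant figures and the probe cross-section to 2 before
#' the ratio is taken (20 nm ribosome -> 1260 nm^2; half RNA -> 630 nm^2;
#' 3.5 nm probe -> 9.6 nm^2; 630/9.6 = 65.625 -> 66 sites). Carrying full
#' precision instead would give 65 sites.
#'
#' @param ribosomeDiameter ribosome diameter (nm).
#' @param rnaSurfaceFraction fraction of the surface that is RNA, in [0, 1].
#' @param probeDiameter probe diameter (nm).
#' @param ribosomeConc cytoplasmic ribosome concentration (uM). The default
#'   10 uM is the printed value for exponentially growing E. coli (the same
#'   source counts ~17000 ribosomes/um^3; the census keeps the printed
#'   concentration and does not attempt to resolve the discrepancy).
#' @return a [SiteGeometry-class] with the intermediate areas, the integer
#'   site count per ribosome and the site concentration (uM).
#' @examples
#' estimateSites(20, 0.5, 3.5, 10)  # 66 sites, 660 uM
#' @export
estimateSites <- function(ribosomeDiameter, rnaSurfaceFraction,
                          probeDiameter, ribosomeConc = 10) {
  if (ribosomeDiameter <= 0 || probeDiameter <= 0) {
    stop("diameters must be > 0")
  }
  if (rnaSurfaceFraction < 0 || rnaSurfaceFraction > 1) {
    stop("'rnaSurfaceFraction' must be in [0, 1]")
  }
  area <- signif(pi * ribosomeDiameter^2, 3)
  rna <- rnaSurfaceFraction * area
  cross <- signif(pi * (probeDiameter / 2)^2, 2)
  n <- as.integer(round(rna / cross))
  new("SiteGeometry",
      ribosomeDiameter = ribosomeDiameter,
      rnaSurfaceFraction = rnaSurfaceFraction,
      probeDiameter = probeDiameter,
      ribosomeConc = ribosomeConc,
      sphereArea = area, rnaArea = rna, probeCrossSection = cross,
      nSites = n, siteConc = n * ribosomeConc)
}

setMethod("show", "SiteGeometry", function(object) {
  cat("SiteGeometry (spherical-ribosome census):\n")
  cat(sprintf("  sphere area      %s nm^2 (d = %g nm)\n",
              format(object@sphereArea), object@ribosomeDiameter))
  cat(sprintf("  RNA surface      %s nm^2 (fraction %g)\n",
              format(object@rnaArea), object@rnaSurfaceFraction))
  cat(sprintf("  probe section    %s nm^2 (d = %g nm)\n",
              format(object@probeCrossSection), object@probeDiameter))
  cat(sprintf("  sites/ribosome   %d\n", object@nSites))
  cat(sprintf("  site conc        %g uM (at %g uM ribosomes)\n",
              object@siteConc, object@ribosomeConc))
})
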