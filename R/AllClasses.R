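#' @import methods
#' @importFrom stats optimize median quantile sd rnorm runif rbinom rlnorm
#'   setNames nlminb mad
#' @importFrom utils read.csv write.csv read.delim write.table head tail
NULL

#' FRAP line-profile stack
#'
#' Container for the FRAP observable: fluorescence intensity along the long
#' axis of a cell, sampled on a uniform spatial grid at a series of
#' post-bleach frame times. Pre-bleach information is kept separately as the
#' mean pre-bleach profile, used to normalise out the illumination profile.
#'
#' @slot positions numeric, strictly increasing uniform grid along the cell
#'   long axis (micrometres).
#' @slot times numeric, strictly increasing frame acquisition times (seconds);
#'   the first entry is the first post-bleach frame.
#' @slot intensities numeric matrix, \code{length(times)} rows by
#'   \code{length(positions)} columns, non-negative arbitrary fluorescence
#'   units.
#' @slot nPrebleach integer count of pre-bleach frames that were averaged.
#' @slot prebleachProfile numeric, mean pre-bleach intensity per position
#'   (same units as \code{intensities}); may be length zero when no
#'   pre-bleach images exist.
#'
#' @seealso [lineProfileStack()], [fitFrap()], [generateFrapStack()]
#' @export
setClass("LineProfileStack",
  slots = c(
    positions = "numeric",
    times = "numeric",
    intensities = "matrix",
    nPrebleach = "integer",
    prebleachProfile = "numeric"
  )
)

setValidity("LineProfileStack", function(object) {
  p <- object@positions
  tt <- object@times
  m <- object@intensities
  msgs <- character()
  if (length(p) < 2L) msgs <- c(msgs, "need at least 2 positions")
  dp <- diff(p)
  if (any(dp <= 0)) msgs <- c(msgs, "positions must be strictly increasing")
  if (length(dp) > 1L &&
      max(abs(dp - dp[1])) > 1e-6 * abs(dp[1])) {
    msgs <- c(msgs, "positions must be uniformly spaced")
  }
  if (length(tt) < 1L || any(diff(tt) <= 0)) {
    msgs <- c(msgs, "times must be strictly increasing")
  }
  if (nrow(m) != length(tt) || ncol(m) != length(p)) {
    msgs <- c(msgs, "intensities must be [n_times x n_positions]")
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    msgs <- c(msgs, "intensities must be finite and non-negative")
  }
  if (object@nPrebleach < 0L) msgs <- c(msgs, "nPrebleach must be >= 0")
  if (length(object@prebleachProfile) &&
      length(object@prebleachProfile) != length(p)) {
    msgs <- c(msgs, "prebleachProfile length must match positions")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a FRAP diffusion fit
#'
#' @slot D fitted diffusion coefficient (um^2/s); \code{NA} when the stack is
#'   non-identifiable.
#' @slot scale fitted multiplicative intensity factor (dimensionless).
#' @slot offset fitted additive background (intensity units).
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical; \code{FALSE} when the optimiser hit the search
#'   bounds or failed.
#' @slot identifiable logical; \code{FALSE} when the stack shows no bleach
#'   contrast above the noise (no D is reported).
#' @slot profileFit fitted intensity matrix, same shape as the input stack.
#' @slot dBounds the search bounds used (um^2/s).
#'
#' @seealso [fitFrap()]
#' @export
setClass("FrapFit",
  slots = c(
    D = "numeric",
    scale = "numeric",
    offset = "numeric",
    rss = "numeric",
    converged = "logical",
    identifiable = "logical",
    profileFit = "matrix",
    dBounds = "numeric"
  )
)

setValidity("FrapFit", function(object) {
  msgs <- character()
  if (isTRUE(object@converged) && isTRUE(object@identifiable) &&
      (!is.finite(object@D) || object@D <= 0)) {
    msgs <- c(msgs, "D must be > 0 when converged")
  }
  if (length(object@rss) && is.finite(object@rss) && object@rss < 0) {
    msgs <- c(msgs, "rss must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Two-state fast-exchange diffusion quartet
#'
#' A probe exchanging rapidly between a free state (diffusion coefficient
#' \code{dFree}) and a bound state (\code{dBound}) moves with a single
#' effective coefficient \code{dEff = fFree*dFree + (1-fFree)*dBound}.
#'
#' @slot dFree free-state diffusion coefficient (um^2/s).
#' @slot dBound bound-state diffusion coefficient (um^2/s).
#' @slot fFree fraction of time spent free, in [0, 1].
#' @slot dEff effective diffusion coefficient (um^2/s).
#'
#' @seealso [twoStateDiffusion()], [effectiveDiffusion()], [freeFraction()]
#' @export
setClass("TwoStateDiffusion",
  slots = c(dFree = "numeric", dBound = "numeric",
            fFree = "numeric", dEff = "numeric")
)

setValidity("TwoStateDiffusion", function(object) {
  msgs <- character()
  f <- object@fFree
  if (f < 0 || f > 1) msgs <- c(msgs, "fFree must be in [0, 1]")
  if (object@dBound > object@dFree) msgs <- c(msgs, "dBound must be <= dFree")
  want <- f * object@dFree + (1 - f) * object@dBound
  tol <- 1e-12 * max(1, abs(want))
  if (abs(object@dEff - want) > tol) {
    msgs <- c(msgs, "dEff must equal fFree*dFree + (1-fFree)*dBound")
  }
  if (length(msgs)) msgs else TRUE
})

#' Geometric ribosome binding-site census
#'
#' Holds the surface-geometry estimate of how many probe-sized, nonspecific
#' binding sites the RNA-covered surface of a ribosome offers, and the
#' resulting cytoplasmic binding-site concentration. Intermediate areas are
#' carried at the precision at which they are conventionally reported
#' (3 significant figures for areas, 2 for the probe cross-section), because
#' the census is a back-of-the-envelope calculation defined on those rounded
#' values.
#'
#' @slot ribosomeDiameter ribosome diameter (nm).
#' @slot rnaSurfaceFraction fraction of the ribosome surface that is RNA.
#' @slot probeDiameter probe (GFP) diameter (nm).
#' @slot ribosomeConc cytoplasmic ribosome concentration (uM).
#' @slot sphereArea ribosome surface area (nm^2, 3 s.f.).
#' @slot rnaArea RNA-exposed surface area (nm^2).
#' @slot probeCrossSection probe cross-sectional area (nm^2, 2 s.f.).
#' @slot nSites integer number of sites per ribosome.
#' @slot siteConc binding-site concentration (uM).
#'
#' @seealso [estimateSites()]
#' @export
setClass("SiteGeometry",
  slots = c(
    ribosomeDiameter = "numeric",
    rnaSurfaceFraction = "numeric",
    probeDiameter = "numeric",
    ribosomeConc = "numeric",
    sphereArea = "numeric",
    rnaArea = "numeric",
    probeCrossSection = "numeric",
    nSites = "integer",
    siteConc = "numeric"
  )
)

#' Ionic-strength-dependent binding free energy parameters
#'
#' Parameters of the screened electrostatic binding model
#' \deqn{\Delta G_b(I) = \Delta G_{nio} + \Delta G_{io0}
#'   \frac{e^{-C_1 \sqrt I}}{1 + C_1 \sqrt I}}
#' where \code{I} is ionic strength (M). \code{dgNio} is the non-ionic
#' component, \code{dgIo0} the electrostatic component at zero ionic
#' strength, and \code{c1} encodes charge separation and non-ionic screening.
#'
#' @slot dgNio non-ionic binding free energy (J/mol).
#' @slot dgIo0 electrostatic binding free energy at I = 0 (J/mol).
#' @slot c1 screening parameter (M^-1/2).
#' @slot temperature absolute temperature (K).
#' @slot rss residual sum of squares in Delta-G space (J^2/mol^2; \code{NA}
#'   when constructed directly rather than fitted).
#'
#' @seealso [bindingFreeEnergy()], [fitIonic()]
#' @export
setClass("IonicBindingParams",
  slots = c(dgNio = "numeric", dgIo0 = "numeric", c1 = "numeric",
            temperature = "numeric", rss = "numeric")
)

setValidity("IonicBindingParams", function(object) {
  if (object@temperature <= 0) "temperature must be > 0" else TRUE
})

#' Charge-dependent effective-diffusion model parameters
#'
#' Parameters of the composite model mapping probe net charge to an effective
#' diffusion coefficient: the electrostatic binding energy is taken linear in
#' charge (\code{dgIo0 = dgPc * charge}), screened by ionic strength, turned
#' into a dissociation constant, a bound fraction at the fixed binding-site
#' concentration, and finally an effective diffusion coefficient between
#' \code{dBound} and \code{dFree}.
#'
#' @slot dgNio non-ionic binding free energy (J/mol).
#' @slot dgPc electrostatic binding free energy per unit net charge
#'   (J mol^-1 charge^-1).
#' @slot c1 screening parameter (M^-1/2).
#' @slot constants named list with fixed quantities \code{dFree}, \code{dBound}
#'   (um^2/s), \code{siteConc} (M), \code{ionicStrength} (M),
#'   \code{temperature} (K).
#' @slot rss residual sum of squares on log10(dEff) (\code{NA} when not
#'   fitted).
#' @slot boundary logical; \code{TRUE} when the fit ran into a no-binding
#'   boundary solution (bound fraction driven to ~0 for all points).
#'
#' @seealso [deffOfCharge()], [fitChargeModel()]
#' @export
setClass("ChargeModelParams",
  slots = c(dgNio = "numeric", dgPc = "numeric", c1 = "numeric",
            constants = "list", rss = "numeric", boundary = "logical")
)

setValidity("ChargeModelParams", function(object) {
  cst <- object@constants
  need <- c("dFree", "dBound", "siteConc", "ionicStrength", "temperature")
  if (!all(need %in% names(cst))) {
    return(paste("constants must contain", paste(need, collapse = ", ")))
  }
  vals <- unlist(cst[need])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    return("constants must be positive and finite")
  }
  if (cst$dFree <= cst$dBound) return("dFree must exceed dBound")
  TRUE
})

#' Set of dissociation constants for titratable protein groups
#'
#' pKa values for the acidic groups (C-terminus, Asp, Glu, Cys, Tyr) and the
#' basic groups (N-terminus, Lys, Arg, His) used by the
#' Henderson-Hasselbalch net-charge calculation. Two named tables ship with
#' the package (see [pkaSet()]): \code{"ipc"} and \code{"classic"}.
#'
#' @slot name identifier of the table.
#' @slot acidic named numeric of pKa values; names from
#'   \{"Cterm", "D", "E", "C", "Y"\}.
#' @slot basic named numeric of pKa values; names from
#'   \{"Nterm", "K", "R", "H"\}.
#'
#' @seealso [pkaSet()], [netCharge()], [isoelectricPoint()]
#' @export
setClass("PkaSet",
  slots = c(name = "character", acidic = "numeric", basic = "numeric")
)

setValidity("PkaSet", function(object) {
  msgs <- character()
  all_pka <- c(object@acidic, object@basic)
  if (any(all_pka <= 0) || any(all_pka >= 14)) {
    msgs <- c(msgs, "all pKa values must lie in (0, 14)")
  }
  if (!"Cterm" %in% names(object@acidic)) {
    msgs <- c(msgs, "acidic set must include the C-terminus ('Cterm')")
  }
  if (!"Nterm" %in% names(object@basic)) {
    msgs <- c(msgs, "basic set must include the N-terminus ('Nterm')")
  }
  if (length(msgs)) msgs else TRUE
})
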