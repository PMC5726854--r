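## 1D diffusion with reflecting (no-flux) boundaries, Crank-Nicolson in time.
## The scheme conserves total intensity exactly (column sums of the update
## matrix are 1) and, because internal sub-steps keep the diffusion number
## D*dt/dx^2 <= 1, the one-step propagator has non-negative entries with unit
## row sums, so the discrete maximum principle holds as well.

# Reflecting-boundary discrete Laplacian (ghost-node form): row sums and
# column sums are both zero, which gives mass conservation and monotonicity.
reflectingLaplacian <- function(n) {
  A <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  A[cbind(idx, idx + 1)] <- 1
  A[cbind(idx + 1, idx)] <- 1
  diag(A) <- -c(1, rep(2, max(0, n - 2)), 1)[seq_len(n)]
  A
}

# One-frame Crank-Nicolson propagator: S^m with S = (I - lam/2 A)^-1 (I + lam/2 A),
# lam = D*(dt/m)/dx^2 <= 1. Computed densely (profiles are 8-16 pixels in
# typical stacks; a few hundred at most in oracle checks).
cnPropagator <- function(n, D, dx, dt) {
  m <- max(1L, ceiling(D * dt / dx^2))
  lam <- D * (dt / m) / dx^2
  A <- reflectingLaplacian(n)
  I <- diag(n)
  S <- solve(I - (lam / 2) * A, I + (lam / 2) * A)
  matPow(S, m)
}

matPow <- function(S, m) {
  P <- diag(nrow(S))
  while (m > 0L) {
    if (m %% 2L == 1L) P <- P %*% S
    S <- S %*% S
    m <- m %/% 2L
  }
  P
}

#' Evolve a fluorescence profile under 1D diffusion in a closed cell
#'
#' Forward-simulates the 1D diffusion equation on a uniform grid with
#' reflecting (no-flux) boundaries at both ends — no particle transfer over
#' the ends of the line — using a Crank-Nicolson integrator with internal
#' sub-stepping so the diffusion number `D*dt/dx^2` never exceeds 1. Total
#' intensity is conserved to machine precision and evolved values stay within
#' the range of the initial profile.
#'
#' @param initialProfile numeric vector, intensity at `times[1] = 0`.
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param dx grid spacing (um), `> 0`. Alternatively give `positions`.
#' @param times sorted times (s) at which to report the profile; must start
#'   at 0.
#' @param positions optional uniform grid (um) from which `dx` is derived;
#'   a non-uniform grid is rejected.
#'
#' @return matrix `[length(times) x length(initialProfile)]`; row 1 is the
#'   initial profile.
#' @examples
#' x <- seq(0, 3, by = 0.375)
#' u0 <- 1 - 0.6 * exp(-(x - 0.3)^2 / (2 * 0.375^2))
#' u <- evolveProfile(u0, D = 10, dx = 0.375, times = seq(0, 0.2, by = 0.004))
#' all.equal(rowSums(u), rep(sum(u0), nrow(u)))
#' @seealso [gaussianProfile()] for the free-space closed form,
#'   [fitFrap()] for the inverse problem.
#' @export
evolveProfile <- function(initialProfile, D, dx = NULL, times,
                          positions = NULL) {
  if (!is.null(positions)) {
    dp <- diff(positions)
    if (length(dp) < 1L || any(dp <= 0) ||
        max(abs(dp - dp[1])) > 1e-6 * abs(dp[1])) {
      stop("'positions' must be a strictly increasing uniform grid")
    }
    dx <- dp[1]
  }
  if (is.null(dx) || !is.finite(dx) || dx <= 0) stop("'dx' must be > 0")
  if (!is.finite(D) || D < 0) stop("'D' must be >= 0")
  if (is.unsorted(times, strictly = FALSE)) stop("'times' must be sorted")
  if (abs(times[1]) > 1e-12) stop("'times' must start at 0")
  u <- as.numeric(initialProfile)
  n <- length(u)
  out <- matrix(0, length(times), n)
  out[1, ] <- u
  if (length(times) == 1L) return(out)
  gaps <- diff(times)
  if (D == 0) {
    for (k in seq_along(gaps)) out[k + 1L, ] <- u
    return(out)
  }
  cache <- list()
  for (k in seq_along(gaps)) {
    key <- sprintf("%.15g", gaps[k])
    P <- cache[[key]]
    if (is.null(P)) {
      P <- cnPropagator(n, D, dx, gaps[k])
      cache[[key]] <- P
    }
    u <- as.numeric(P %*% u)
    out[k + 1L, ] <- u
  }
  out
}

#' Free-space Gaussian spreading profile
#'
#' Closed-form solution for an initial Gaussian of standard deviation
#' `sigma0` spreading by free 1D diffusion: at time `t` the profile is a
#' Gaussian of variance `sigma0^2 + 2*D*t` (variances of independent
#' Gaussian displacements add under convolution). Used as the independent
#' oracle for [evolveProfile()] on domains large enough that the boundaries
#' are irrelevant.
#'
#' @param sigma0 initial standard deviation (um), `> 0`.
#' @param D diffusion coefficient (um^2/s), `>= 0`.
#' @param positions evaluation grid (um), uniform.
#' @param t time (s), `>= 0`.
#' @param amplitude total mass: the discrete `sum(profile) * dx` equals this.
#' @param center centre of the Gaussian (um).
#'
#' @return numeric intensity vector over `positions`.
#' @examples
#' x <- seq(-20, 20, by = 0.05)
#' g <- gaussianProfile(0.5, D = 2, positions = x, t = 0.25)
#' # empirical SD is sqrt(0.5^2 + 2*2*0.25) = sqrt(1.25)
#' sqrt(sum(g * x^2) / sum(g))
#' @export
gaussianProfile <- function(sigma0, D, positions, t, amplitude = 1,
                            center = 0) {
  if (!is.finite(sigma0) || sigma0 <= 0) stop("'sigma0' must be > 0")
  if (!is.finite(t) || t < 0) stop("'t' must be >= 0")
  if (!is.finite(D) || D < 0) stop("'D' must be >= 0")
  v <- sigma0^2 + 2 * D * t
  dx <- diff(positions)[1]
  g <- exp(-(positions - center)^2 / (2 * v))
  g * (amplitude / (sum(g) * dx))
}
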