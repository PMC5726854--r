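## Seed-reproducible generators standing in for the microscope and for
## UniProt downloads: noisy FRAP stacks with known D, two-state switching
## random walks, and stand-in proteomes. All generators are pure functions of
## (configuration, seed).

#' Generate a synthetic FRAP line-profile stack with known D
#'
#' Emulates a pole-bleach FRAP acquisition in a rod-shaped cell: a flat
#' pre-bleach profile, a first post-bleach frame equal to
#' `1 - bleachDepth * Gaussian(bleachCenter, bleachWidth)`, forward evolution
#' by [evolveProfile()] at the true `D`, and i.i.d. additive Gaussian read
#' noise per pixel per frame. Defaults mirror a standard fast-probe
#' acquisition: 8 pixels, 50 frames, 4 ms interval, in a 3 um cell; the
#' bleach is a Gaussian dip of depth 0.6 and width one pixel near a pole.
#'
#' @param dTrue true diffusion coefficient (um^2/s).
#' @param cellLength cell length (um).
#' @param nPixels number of pixels along the long axis.
#' @param bleachCenter bleach centre (um); defaults to one pixel from the
#'   pole.
#' @param bleachWidth Gaussian sigma of the bleach (um); defaults to one
#'   pixel.
#' @param bleachDepth fractional depth of the bleach, in (0, 1].
#' @param nFrames number of post-bleach frames.
#' @param frameInterval time between frames (s).
#' @param noiseSd read-noise standard deviation as a fraction of the
#'   pre-bleach intensity.
#' @param noiseModel `"gaussian"` (homoscedastic, the default) or
#'   `"poisson"` (shot noise scaled so the flat-field sd equals `noiseSd`).
#' @param nPrebleach number of pre-bleach frames averaged into the stored
#'   profile.
#' @param seed integer seed; stacks are byte-identical for equal seeds.
#' @return a [LineProfileStack-class].
#' @examples
#' stack <- generateFrapStack(dTrue = 10, noiseSd = 0.02, seed = 7)
#' fitFrap(stack)
#' @export
generateFrapStack <- function(dTrue, cellLength = 3, nPixels = 8,
                              bleachCenter = NULL, bleachWidth = NULL,
                              bleachDepth = 0.6, nFrames = 50,
                              frameInterval = 0.004, noiseSd = 0.02,
                              noiseModel = c("gaussian", "poisson"),
                              nPrebleach = 3L, seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(dTrue >= 0, cellLength > 0, nPixels >= 4, nFrames >= 3,
            frameInterval > 0, noiseSd >= 0,
            bleachDepth > 0, bleachDepth <= 1)
  dx <- cellLength / nPixels
  x <- seq(dx / 2, cellLength - dx / 2, by = dx)  # pixel centres
  if (is.null(bleachCenter)) bleachCenter <- x[1]
  if (is.null(bleachWidth)) bleachWidth <- dx
  if (bleachCenter < 0 || bleachCenter > cellLength) {
    stop("'bleachCenter' must lie within the cell")
  }
  if (bleachWidth > cellLength) {
    warning("bleach is wider than the cell; the stack may carry no contrast")
  }
  u0 <- 1 - bleachDepth * exp(-(x - bleachCenter)^2 / (2 * bleachWidth^2))
  times <- seq(0, by = frameInterval, length.out = nFrames)
  clean <- evolveProfile(u0, dTrue, dx = dx, times = times)
  withr::with_seed(as.integer(seed), {
    noisy <- if (noiseSd == 0) {
      clean
    } else if (noiseModel == "gaussian") {
      clean + matrix(rnorm(length(clean), sd = noiseSd),
                     nrow(clean), ncol(clean))
    } else {
      # shot noise: counts scaled so a flat field of 1 has sd = noiseSd
      counts <- 1 / noiseSd^2
      matrix(stats::rpois(length(clean), lambda = pmax(clean, 0) * counts),
             nrow(clean), ncol(clean)) / counts
    }
    noisy <- pmax(noisy, 0)
    pb <- pmax(1 + rnorm(length(x), sd = noiseSd / sqrt(nPrebleach)), 0)
  })
  lineProfileStack(x, times, noisy, nPrebleach = as.integer(nPrebleach),
                   prebleachProfile = pb)
}

#' Acquisition settings matched to an expected diffusion speed
#'
#' FRAP acquisitions must resolve the recovery: fast probes are recorded at
#' 8 pixels and 50 frames of 4 ms, slow probes at 16 pixels and 100 frames
#' with a longer time step — the same strategy the original measurements
#' used (4 ms exposures for fast negative probes, 8-100 ms steps or longer
#' for slow positive ones). The frame interval is chosen so the record spans
#' roughly three diffusion times `L^2/(pi^2 D)`, with a 4 ms floor and a 1 s
#' cap.
#'
#' @param D expected diffusion coefficient (um^2/s).
#' @param cellLength cell length (um).
#' @return list with `nPixels`, `nFrames` and `frameInterval` (s).
#' @export
frapAcquisition <- function(D, cellLength = 3) {
  stopifnot(D > 0)
  tau <- cellLength^2 / (pi^2 * D)
  nFrames <- if (D >= 1) 50L else 100L
  list(nPixels = if (D >= 1) 8L else 16L, nFrames = nFrames,
       frameInterval = min(1, max(0.004, 3 * tau / nFrames)))
}

#' Simulate a two-state switching random walk and estimate its D_eff
#'
#' Particles alternate between a free state (diffusion coefficient `dFree`)
#' and a bound state (`dBound`), switching with first-order rates `kBind`
#' (free to bound) and `kRelease` (bound to free); per step of length `dt`
#' the displacement is Gaussian with variance `2 * D(state) * dt`. The
#' stationary free fraction is `kRelease / (kBind + kRelease)`. Under fast
#' exchange the end-to-end displacements are Gaussian with variance
#' `2 * dEff * t`, where `dEff` is the time-weighted average of the two
#' coefficients; under slow exchange the displacement distribution is a
#' two-Gaussian mixture (positive excess kurtosis).
#'
#' @param dFree,dBound state diffusion coefficients (um^2/s).
#' @param kBind,kRelease switching rates (1/s), `>= 0`.
#' @param dt time step (s); must satisfy `dt * max(kBind, kRelease) <= 0.1`
#'   for first-order switching to be accurate (violations are rejected, not
#'   silently degraded).
#' @param nSteps steps per particle.
#' @param nParticles number of independent particles.
#' @param seed integer seed.
#' @return list with `dEff` (mean of per-particle `x(T)^2 / (2T)`), `se`
#'   (standard error over particles), `fFreeEmpirical` (fraction of particle
#'   time spent free), `displacements` (end-to-end, um), `totalTime` (s).
#' @examples
#' w <- simulateSwitchingWalk(10, 0.04, kBind = 1000, kRelease = 1000,
#'                            dt = 1e-4, nSteps = 2000, nParticles = 500,
#'                            seed = 1)
#' w$dEff  # ~ 0.5*10 + 0.5*0.04 = 5.02
#' @export
simulateSwitchingWalk <- function(dFree, dBound, kBind, kRelease,
                                  dt = 1e-4, nSteps = 5000L,
                                  nParticles = 1000L, seed = 1L) {
  stopifnot(dFree >= 0, dBound >= 0, kBind >= 0, kRelease >= 0, dt > 0,
            nSteps >= 1, nParticles >= 2)
  if (dt * max(kBind, kRelease) > 0.1) {
    stop("'dt' too coarse: require dt * max(kBind, kRelease) <= 0.1")
  }
  fStat <- if (kBind + kRelease == 0) 1 else kRelease / (kBind + kRelease)
  pBind <- kBind * dt
  pRel <- kRelease * dt
  sdF <- sqrt(2 * dFree * dt)
  sdB <- sqrt(2 * dBound * dt)
  withr::with_seed(as.integer(seed), {
    free <- runif(nParticles) < fStat
    x <- numeric(nParticles)
    timeFree <- 0
    for (s in seq_len(nSteps)) {
      x <- x + rnorm(nParticles, sd = ifelse(free, sdF, sdB))
      timeFree <- timeFree + sum(free)
      u <- runif(nParticles)
      free <- ifelse(free, u >= pBind, u < pRel)
    }
  })
  totalTime <- nSteps * dt
  dHat <- x^2 / (2 * totalTime)
  list(dEff = mean(dHat), se = sd(dHat) / sqrt(nParticles),
       fFreeEmpirical = timeFree / (nSteps * nParticles),
       displacements = x, totalTime = totalTime)
}

#' Generate a stand-in proteome with FASTA/TSV serialisation
#'
#' Draws random protein sequences whose charged-residue frequencies are
#' calibrated so the expected net charge per protein (ipc mode, pH 7.5)
#' equals `compositionBias`: starting from a uniform composition, probability
#' mass is shifted between Lys and Asp until the expected per-residue charge
#' at the mean length matches the target. A chosen fraction of records is
#' tagged cytosolic (GO:0005829), and copy numbers are log-normal
#' (median ~200 copies, sdlog 1.5 — a typical spread for bacterial
#' proteomes).
#'
#' @param nProteins number of records.
#' @param lengthRange integer range of sequence lengths (residues).
#' @param compositionBias target mean net charge per protein at pH 7.5.
#' @param fractionCytoplasmic fraction of records tagged GO:0005829; the
#'   count is exact (`round(fraction * n)`), assigned to the first records.
#' @param seed integer seed; output is byte-identical per seed.
#' @param dir optional directory: when given, writes `proteome.fasta`,
#'   `go.tsv`, `copy_number.tsv` there.
#' @return list with `proteome` (an `AAStringSet` with `go_terms` and
#'   `copy_number` metadata) and, when `dir` is given, `files` (named paths).
#' @examples
#' gp <- generateProteome(nProteins = 50, compositionBias = -5, seed = 2)
#' mean(proteomeChargeTable(gp$proteome)$net_charge)
#' @export
generateProteome <- function(nProteins = 100, lengthRange = c(80L, 400L),
                             compositionBias = 0, fractionCytoplasmic = 0.5,
                             seed = 1L, dir = NULL) {
  stopifnot(nProteins >= 1, lengthRange[1] >= 10,
            lengthRange[2] >= lengthRange[1],
            fractionCytoplasmic >= 0, fractionCytoplasmic <= 1)
  pka <- pkaSet("ipc")
  ph <- 7.5
  qOf <- function(aa) {  # expected charge contribution of one residue
    if (aa %in% names(pka@acidic)) return(-1 / (1 + 10^(pka@acidic[[aa]] - ph)))
    if (aa %in% names(pka@basic)) return(1 / (1 + 10^(ph - pka@basic[[aa]])))
    0
  }
  zRes <- vapply(AA_STANDARD, qOf, numeric(1))
  prob <- setNames(rep(1 / 20, 20), AA_STANDARD)
  meanLen <- mean(lengthRange)
  zTermini <- qOf("K") * 0 + (1 / (1 + 10^(ph - pka@basic[["Nterm"]]))) -
    (1 / (1 + 10^(pka@acidic[["Cterm"]] - ph)))
  # shift mass between K (+1) and D (-1) to hit the target mean charge
  base <- sum(prob * zRes) * meanLen + zTermini
  delta <- (compositionBias - base) / (meanLen * (zRes[["K"]] - zRes[["D"]]))
  delta <- max(min(delta, prob[["D"]] - 1e-4), -(prob[["K"]] - 1e-4))
  prob[["K"]] <- prob[["K"]] + delta
  prob[["D"]] <- prob[["D"]] - delta
  withr::with_seed(as.integer(seed), {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nProteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_STANDARD, L, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    copy <- round(rlnorm(nProteins, meanlog = log(200), sdlog = 1.5))
  })
  ids <- sprintf("SYN%04d", seq_len(nProteins))
  nCyto <- round(fractionCytoplasmic * nProteins)
  go <- c(rep("GO:0005829", nCyto), rep("", nProteins - nCyto))
  proteome <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(proteome) <- S4Vectors::DataFrame(
    go_terms = go, copy_number = pmax(copy, 1))
  out <- list(proteome = proteome)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "proteome.fasta")
    Biostrings::writeXStringSet(proteome, fa)
    goPath <- file.path(dir, "go.tsv")
    write.table(data.frame(id = ids, go_terms = go), goPath,
                sep = "\t", row.names = FALSE, quote = FALSE)
    cnPath <- file.path(dir, "copy_number.tsv")
    write.table(data.frame(id = ids, copy_number = pmax(copy, 1)), cnPath,
                sep = "\t", row.names = FALSE, quote = FALSE)
    out$files <- c(fasta = fa, go = goPath, copy = cnPath)
  }
  out
}
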