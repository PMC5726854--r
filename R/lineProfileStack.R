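#' Construct a FRAP line-profile stack
#'
#' @param positions uniform, strictly increasing grid along the cell long
#'   axis (um).
#' @param times strictly increasing frame times (s); first entry is the first
#'   post-bleach frame. By convention `times[1]` need not be zero; fitting is
#'   relative to the first frame.
#' @param intensities numeric matrix `[length(times) x length(positions)]`.
#' @param nPrebleach number of pre-bleach frames that were averaged.
#' @param prebleachProfile mean pre-bleach intensity per position, or
#'   `numeric(0)` when unavailable.
#'
#' @return a [LineProfileStack-class] object.
#' @examples
#' x <- seq(0, 3, length.out = 8)
#' stack <- lineProfileStack(x, c(0, 0.004), rbind(rep(1, 8), rep(1, 8)))
#' positions(stack)
#' @export
lineProfileStack <- function(positions, times, intensities,
                             nPrebleach = 0L,
                             prebleachProfile = numeric(0)) {
  new("LineProfileStack",
      positions = as.numeric(positions),
      times = as.numeric(times),
      intensities = as.matrix(intensities),
      nPrebleach = as.integer(nPrebleach),
      prebleachProfile = as.numeric(prebleachProfile))
}

#' @rdname cytodiff-accessors
setMethod("positions", "LineProfileStack", function(x) x@positions)

#' @rdname cytodiff-accessors
setMethod("frameTimes", "LineProfileStack", function(x) x@times)

#' @rdname cytodiff-accessors
setMethod("intensities", "LineProfileStack", function(x) x@intensities)

#' @rdname cytodiff-accessors
setMethod("prebleachProfile", "LineProfileStack",
          function(x) x@prebleachProfile)

#' @rdname cytodiff-accessors
setMethod("diffusionCoef", "FrapFit", function(x) x@D)

setMethod("show", "LineProfileStack", function(object) {
  p <- object@positions
  cat("LineProfileStack:", length(object@times), "frames x",
      length(p), "positions\n")
  cat(sprintf("  grid: %.3g..%.3g um (dx = %.3g um)\n",
              p[1], p[length(p)], p[2] - p[1]))
  tt <- object@times
  cat(sprintf("  times: %.4g..%.4g s\n", tt[1], tt[length(tt)]))
  cat(sprintf("  pre-bleach frames averaged: %d (%s profile)\n",
              object@nPrebleach,
              if (length(object@prebleachProfile)) "with" else "no"))
})

setMethod("show", "FrapFit", function(object) {
  if (!object@identifiable) {
    cat("FrapFit: non-identifiable stack (no bleach contrast); no D reported\n")
    return(invisible(NULL))
  }
  cat(sprintf("FrapFit: D = %.4g um^2/s (%sconverged)\n", object@D,
              if (object@converged) "" else "NOT "))
  cat(sprintf("  scale = %.4g, offset = %.4g, rss = %.4g\n",
              object@scale, object@offset, object@rss))
  cat(sprintf("  search bounds: [%.3g, %.3g] um^2/s\n",
              object@dBounds[1], object@dBounds[2]))
})

#' Read and write line-profile stacks as CSV
#'
#' The on-disk dialect is a wide CSV: first column `position_um`, one further
#' column per frame whose header is the frame time in seconds. The mean
#' pre-bleach profile, when present, lives in a sibling file
#' `<stem>_prebleach.csv` with columns `position_um,intensity`.
#'
#' @param stack a [LineProfileStack-class].
#' @param path CSV path of the frame table.
#' @return `readLineProfileStack()` a [LineProfileStack-class];
#'   `writeLineProfileStack()` the main path, invisibly.
#' @export
writeLineProfileStack <- function(stack, path) {
  m <- t(intensities(stack))
  df <- data.frame(position_um = positions(stack), m, check.names = FALSE)
  names(df)[-1] <- format(frameTimes(stack), digits = 15, trim = TRUE,
                          scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (length(prebleachProfile(stack))) {
    pb <- data.frame(position_um = positions(stack),
                     intensity = prebleachProfile(stack))
    write.csv(pb, prebleachPath(path), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname writeLineProfileStack
#' @param nPrebleach number of pre-bleach frames the sibling profile averages
#'   (metadata only).
#' @export
readLineProfileStack <- function(path, nPrebleach = 0L) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(names(df)[1] == "position_um")
  times <- as.numeric(names(df)[-1])
  if (any(is.na(times))) stop("frame column headers must be times in seconds")
  pb <- numeric(0)
  pbp <- prebleachPath(path)
  if (file.exists(pbp)) {
    pbdf <- read.csv(pbp)
    pb <- pbdf$intensity
    if (nPrebleach == 0L) nPrebleach <- 1L
  }
  lineProfileStack(df$position_um, times,
                   t(as.matrix(df[, -1, drop = FALSE])),
                   nPrebleach = nPrebleach, prebleachProfile = pb)
}

prebleachPath <- function(path) {
  sub("\\.csv$", "_prebleach.csv", path)
}
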