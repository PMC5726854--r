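# Shared fixtures, built in code at test time.

# deterministic random amino-acid sequence
randomProtein <- function(n, seed) {
  withr::with_seed(seed, {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                 replace = TRUE), collapse = "")
  })
}

# brute-force pI oracle: 0.001-pH grid scan minimiser of |Z|, written
# independently of the package (its own residue counting and
# Henderson-Hasselbalch evaluation, vectorised over the grid)
gridScanPI <- function(sequence, mode = "ipc") {
  tab <- read.csv(system.file(
    "extdata",
    if (mode == "ipc") "pka_ipc_protein.csv" else "pka_classic.csv",
    package = "cytodiff"))
  chars <- strsplit(sequence, "")[[1]]
  grid <- seq(0.001, 13.999, by = 0.001)
  z <- numeric(length(grid))
  for (i in seq_len(nrow(tab))) {
    g <- tab$group[i]
    n <- if (g %in% c("Nterm", "Cterm")) 1 else sum(chars == g)
    if (n == 0) next
    z <- z + if (tab$type[i] == "basic") {
      n / (1 + 10^(grid - tab$pka[i]))
    } else {
      -n / (1 + 10^(tab$pka[i] - grid))
    }
  }
  grid[which.min(abs(z))]
}

# excess kurtosis
excessKurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

# published constants used across tests
ECOLI <- list(dFree = 10, dBound = 0.04, siteConc = 660, ionicStrength = 0.2)
KD_TRIPLE <- data.frame(
  ionicStrength = c(0.2, 0.8, 2.1),     # E. coli, L. lactis, Hfx. volcanii
  kd = c(6.7e-6, 65e-6, 155e-6))        # M
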