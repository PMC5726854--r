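## Proteome-wide charge/pI analysis. Proteomes are Biostrings::AAStringSet
## objects whose mcols() carry optional per-protein metadata: `copy_number`
## (numeric) and `go_terms` (semicolon-separated GO identifiers, mirroring a
## UniProt column export).

#' Read a proteome with optional GO annotation and copy numbers
#'
#' Reads a multi-record FASTA into an `AAStringSet` and attaches, via
#' `mcols()`, GO annotations and protein copy numbers from tab-separated
#' files keyed by sequence identifier. The GO TSV has columns
#' `id<TAB>go_terms` (semicolon-separated GO IDs); the copy-number TSV has
#' `id<TAB>copy_number`.
#'
#' @param fasta path to a FASTA file of amino-acid sequences.
#' @param goTsv optional path to the GO annotation TSV.
#' @param copyTsv optional path to the copy-number TSV.
#' @return an `AAStringSet` with `mcols()` columns `go_terms` (character,
#'   `""` when unannotated) and `copy_number` (numeric, `NA` when unknown).
#' @examples
#' \dontrun{prot <- readProteome("proteome.fasta", goTsv = "go.tsv")}
#' @export
readProteome <- function(fasta, goTsv = NULL, copyTsv = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- S4Vectors::DataFrame(
    go_terms = rep("", length(seqs)),
    copy_number = rep(NA_real_, length(seqs)),
    row.names = names(seqs))
  if (!is.null(goTsv)) {
    go <- read.delim(goTsv, stringsAsFactors = FALSE)
    idx <- match(names(seqs), go[[1]])
    meta$go_terms <- ifelse(is.na(idx), "", go[[2]][idx])
  }
  if (!is.null(copyTsv)) {
    cn <- read.delim(copyTsv, stringsAsFactors = FALSE)
    idx <- match(names(seqs), cn[[1]])
    meta$copy_number <- as.numeric(cn[[2]][idx])
  }
  S4Vectors::mcols(seqs) <- meta
  seqs
}

#' Keep only cytoplasmic/cytosolic proteins by GO annotation
#'
#' Retains records whose GO term set intersects the query set; the defaults
#' are the UniProt labels for cytoplasm (GO:0005737) and cytosol
#' (GO:0005829). Records without annotation are dropped. The retained count
#' is reported as a message.
#'
#' @param proteome an `AAStringSet` with a `go_terms` metadata column
#'   (semicolon-separated IDs; possibly empty strings).
#' @param goTerms character vector of GO identifiers to select on.
#' @return the filtered `AAStringSet`.
#' @export
filterCytoplasmic <- function(proteome,
                              goTerms = c("GO:0005737", "GO:0005829")) {
  meta <- S4Vectors::mcols(proteome)
  if (is.null(meta) || !"go_terms" %in% colnames(meta)) {
    stop("proteome records must carry a 'go_terms' metadata column")
  }
  sets <- strsplit(as.character(meta$go_terms), ";\\s*")
  keep <- vapply(sets, function(s) length(intersect(s, goTerms)) > 0,
                 logical(1))
  message(sum(keep), " of ", length(proteome),
          " proteins carry a cytoplasm/cytosol label")
  proteome[keep]
}

#' Per-protein net charge and isoelectric point table
#'
#' @param proteome an `AAStringSet` (metadata columns are carried through).
#' @param ph pH for the net-charge evaluation (default 7.5, cytoplasmic).
#' @param mode charge mode, see [netCharge()].
#' @param pka optional [PkaSet-class] override.
#' @return a `data.frame` with columns `id`, `length`, `net_charge`, `pi`,
#'   plus `copy_number`/`go_terms` when present.
#' @export
proteomeChargeTable <- function(proteome, ph = 7.5,
                                mode = c("ipc", "counting"), pka = NULL) {
  mode <- match.arg(mode)
  if (is.null(pka)) pka <- pkaSet(if (mode == "ipc") "ipc" else "classic")
  ids <- names(proteome)
  if (is.null(ids)) ids <- as.character(seq_along(proteome))
  seqs <- as.character(proteome)
  z <- vapply(seq_along(seqs), function(i) {
    netCharge(seqs[i], ph, mode = mode, pka = pka, id = ids[i])
  }, numeric(1))
  pi <- vapply(seq_along(seqs), function(i) {
    as.numeric(isoelectricPoint(seqs[i], mode = mode, pka = pka, id = ids[i]))
  }, numeric(1))
  out <- data.frame(id = ids, length = nchar(seqs), net_charge = z, pi = pi,
                    stringsAsFactors = FALSE)
  meta <- S4Vectors::mcols(proteome)
  if (!is.null(meta)) {
    if ("copy_number" %in% colnames(meta)) {
      out$copy_number <- as.numeric(meta$copy_number)
    }
    if ("go_terms" %in% colnames(meta)) {
      out$go_terms <- as.character(meta$go_terms)
    }
  }
  out
}

#' Proteome-wide pI and net-charge histograms
#'
#' Computes per-protein net charge (at `ph`) and isoelectric point, then bins
#' them: net charge in unit-width bins centred on integers, pI in 0.25-pH
#' bins over (0, 14). With `weighting = "copy_number"` each protein
#' contributes its copy number instead of 1, turning the gene-count
#' distribution into an abundance-weighted one.
#'
#' @inheritParams proteomeChargeTable
#' @param weighting `"none"` (one count per gene) or `"copy_number"`.
#' @return a list with elements `table` (the per-protein table), `charge`
#'   and `pi` (data frames `mid`, `count` of bin midpoints and, possibly
#'   weighted, counts).
#' @examples
#' prot <- generateProteome(nProteins = 20, seed = 1)$proteome
#' h <- proteomeDistribution(prot)
#' head(h$charge)
#' @export
proteomeDistribution <- function(proteome, ph = 7.5,
                                 weighting = c("none", "copy_number"),
                                 mode = c("ipc", "counting"), pka = NULL) {
  weighting <- match.arg(weighting)
  if (length(proteome) < 1L) stop("need at least one protein record")
  tab <- proteomeChargeTable(proteome, ph = ph, mode = mode, pka = pka)
  w <- rep(1, nrow(tab))
  if (weighting == "copy_number") {
    if (is.null(tab$copy_number) || anyNA(tab$copy_number)) {
      stop("copy-number weighting requested but copy numbers are absent")
    }
    w <- tab$copy_number
  }
  chargeBin <- round(tab$net_charge)
  chargeMids <- seq(min(chargeBin), max(chargeBin))
  charge <- data.frame(
    mid = chargeMids,
    count = vapply(chargeMids, function(m) sum(w[chargeBin == m]),
                   numeric(1)))
  piBreaks <- seq(0, 14, by = 0.25)
  piIdx <- findInterval(tab$pi, piBreaks, rightmost.closed = TRUE)
  piMids <- piBreaks[-length(piBreaks)] + 0.125
  pi <- data.frame(
    mid = piMids,
    count = vapply(seq_along(piMids), function(i) sum(w[piIdx == i]),
                   numeric(1)))
  list(table = tab, charge = charge, pi = pi)
}
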