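#' @importFrom stats aggregate approx cor isoreg median p.adjust pnorm
#'   quantile rnorm runif sd setNames t.test var
#' @importFrom utils read.delim write.table head tail
NULL

# Monoisotopic residue masses (Da). Cys carries fixed carbamidomethyl
# (+57.021464, iodoacetamide alkylation).
.RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.021464, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
.MASS_PROTON <- 1.007276466
.MASS_WATER  <- 18.0105646863

# Split "PEPT[+15.994915]IDE" into residues; bracketed offsets attach to the
# preceding residue.
.parse_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  res <- character(0)
  mods <- numeric(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- match("]", chars[i:length(chars)])
      if (is.na(j)) stop("unterminated modification bracket in '", sequence, "'")
      if (length(res) == 0L)
        stop("modification before first residue in '", sequence, "'")
      off <- suppressWarnings(as.numeric(paste(chars[(i + 1):(i + j - 2)],
                                               collapse = "")))
      if (is.na(off)) stop("non-numeric modification in '", sequence, "'")
      mods[length(res)] <- mods[length(res)] + off
      i <- i + j
    } else {
      if (!ch %in% names(.RESIDUE_MASS))
        stop("invalid residue '", ch, "' at position ", length(res) + 1L,
             " of '", sequence, "'")
      res <- c(res, ch)
      mods <- c(mods, 0)
      i <- i + 1L
    }
  }
  list(residues = res, mod_mass = mods)
}

#' Strip bracketed modifications from a peptide sequence
#'
#' @param sequence modified peptide string, e.g. `"C[+57.02]PEPK"`.
#' @return plain residue string.
#' @export
strip_modifications <- function(sequence) {
  gsub("\\[[^]]*\\]", "", sequence)
}

#' Monoisotopic precursor m/z of a peptide
#'
#' Computes `(M + z * proton) / z` from standard monoisotopic residue masses.
#' Cysteine is treated as carbamidomethylated (fixed +57.021464 Da); other
#' modifications can be written inline as bracketed mass offsets.
#'
#' @param sequence peptide string of uppercase residues, optionally with
#'   bracketed mass offsets (`"M[+15.994915]"`).
#' @param charge positive integer charge state.
#' @return precursor m/z in Th.
#' @examples
#' precursor_mz("G", 1)       # 76.039
#' precursor_mz("PEPTIDEK", 2)
#' @export
precursor_mz <- function(sequence, charge) {
  stopifnot(length(charge) == 1L, charge >= 1, charge == round(charge))
  p <- .parse_sequence(sequence)
  m <- sum(.RESIDUE_MASS[p$residues]) + sum(p$mod_mass) + .MASS_WATER
  (m + charge * .MASS_PROTON) / charge
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R, suppressed when the next residue is P, and
#' returns every peptide with at most `missed_cleavages` internal cleavage
#' sites, ordered by start position (then by length at equal start).
#'
#' @param sequence protein sequence (plain residues, no modifications).
#' @param missed_cleavages maximum number of internal missed cleavage sites
#'   (integer >= 0).
#' @return character vector of peptides.
#' @examples
#' digest("AKCR", 0)  # "AK" "CR"
#' digest("AKPR", 0)  # "AKPR" (KP bond not cleaved)
#' digest("AKCR", 1)  # adds "AKCR"
#' @export
digest <- function(sequence, missed_cleavages = 0L) {
  stopifnot(missed_cleavages >= 0)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(.RESIDUE_MASS))
  if (length(bad))
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1])
  n <- length(chars)
  # cleavage sites: after position i when chars[i] in K/R and chars[i+1] != P
  cut_after <- which(chars %in% c("K", "R") & c(chars[-1], "") != "P")
  cut_after <- cut_after[cut_after < n]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  k <- length(starts)
  out <- character(0)
  ord_start <- integer(0)
  for (i in seq_len(k)) {
    for (j in i:min(k, i + missed_cleavages)) {
      out <- c(out, substr(sequence, starts[i], ends[j]))
      ord_start <- c(ord_start, starts[i])
    }
  }
  out[order(ord_start, nchar(out))]
}

#' Count internal missed cleavage sites of a peptide
#'
#' @param peptide peptide string (modifications allowed; they are stripped).
#' @return integer count of internal K/R sites not followed by P.
#' @export
missed_cleavage_count <- function(peptide) {
  s <- strip_modifications(peptide)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(0L)
  sum(chars[-n] %in% c("K", "R") & chars[-1] != "P")
}

#' Read a FASTA proteome into a named sequence map
#'
#' @param path FASTA file path.
#' @return named character vector, accession (first token of the header) to
#'   amino-acid sequence.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  validate_proteome(seqs)
  seqs
}

#' Validate a proteome map
#'
#' Checks that all sequences contain only standard residue letters.
#'
#' @param proteome named character vector (accession -> sequence).
#' @return the proteome, invisibly.
#' @export
validate_proteome <- function(proteome) {
  stopifnot(is.character(proteome), length(proteome) >= 1L,
            !is.null(names(proteome)))
  ok <- grepl(paste0("^[", paste(names(.RESIDUE_MASS), collapse = ""), "]+$"),
              proteome)
  if (!all(ok))
    stop("invalid residues in proteome entries: ",
         paste(names(proteome)[!ok], collapse = ", "))
  invisible(proteome)
}

#' Peptides shared between two proteomes
#'
#' Digests every protein in both proteomes and returns the peptides produced
#' by at least one protein in each. Used to drop analyte peptides that the
#' background matrix species (e.g. chicken serum under a human analyte) also
#' produces, so matrix-matched dilution curves stay interpretable.
#'
#' @param a,b proteome maps (named character vectors).
#' @param missed_cleavages passed to [digest()].
#' @return character vector of shared peptide sequences (sorted).
#' @export
shared_peptides <- function(a, b, missed_cleavages = 0L) {
  validate_proteome(a); validate_proteome(b)
  pep_a <- unique(unlist(lapply(a, digest, missed_cleavages = missed_cleavages),
                         use.names = FALSE))
  pep_b <- unique(unlist(lapply(b, digest, missed_cleavages = missed_cleavages),
                         use.names = FALSE))
  sort(intersect(pep_a, pep_b))
}
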