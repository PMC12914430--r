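#' A single fragment-ion chromatogram
#'
#' @param fragment_mz fragment m/z (Th).
#' @param ion_label fragment label, e.g. `"y7+"`.
#' @param times retention times in minutes, strictly increasing.
#' @param intensities non-negative counts, same length as `times`.
#' @return object of class `transition_trace`.
#' @export
transition_trace <- function(fragment_mz, ion_label, times, intensities) {
  stopifnot(is.numeric(fragment_mz), fragment_mz > 0)
  if (length(times) != length(intensities))
    stop("transition ", ion_label, ": times and intensities differ in length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("transition ", ion_label, ": times not strictly increasing")
  if (any(intensities < 0))
    stop("transition ", ion_label, ": negative intensities")
  structure(list(fragment_mz = as.numeric(fragment_mz),
                 ion_label = as.character(ion_label),
                 times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "transition_trace")
}

#' One precursor entry of a chromatogram library
#'
#' @param sequence peptide sequence (bracketed mass offsets allowed).
#' @param charge precursor charge (>= 1).
#' @param protein_ids character vector of protein accessions.
#' @param retention_time apex retention time, minutes.
#' @param transitions list of [transition_trace()] objects (>= 1).
#' @param precursor_mz optional stored m/z; recomputed from the sequence when
#'   `NULL` and checked against the stored value (0.01 Th) otherwise.
#' @param peak optional [peak_feature()] from peak detection.
#' @param score optional library search score (parsed and preserved, unused).
#' @return object of class `chrom_entry`.
#' @export
chrom_entry <- function(sequence, charge, protein_ids, retention_time,
                        transitions, precursor_mz = NULL, peak = NULL,
                        score = NA_real_) {
  mz <- precursor_mz(sequence, charge)
  if (!is.null(precursor_mz) && !is.na(precursor_mz)) {
    if (abs(precursor_mz - mz) > 0.01)
      stop("stored precursor m/z ", precursor_mz, " for ", sequence, "/",
           charge, " disagrees with computed ", round(mz, 4), " by > 0.01 Th")
    mz <- as.numeric(precursor_mz)
  }
  if (length(transitions) < 1L)
    stop("entry ", sequence, "/", charge, " has no transitions")
  ok <- vapply(transitions, inherits, logical(1), "transition_trace")
  stopifnot(all(ok))
  structure(list(sequence = sequence, charge = as.integer(charge),
                 precursor_mz = mz,
                 protein_ids = as.character(protein_ids),
                 retention_time = as.numeric(retention_time),
                 transitions = transitions, peak = peak,
                 score = as.numeric(score)),
            class = "chrom_entry")
}

#' A chromatogram library
#'
#' The per-precursor record set produced by gas-phase-fractionated DIA:
#' each entry carries fragment chromatograms, an apex retention time and
#' protein mapping for one (sequence, charge) precursor.
#'
#' @param entries list of [chrom_entry()] objects.
#' @param gradient_length LC gradient length, minutes.
#' @param metadata free-form named list.
#' @return object of class `chrom_library`.
#' @export
chrom_library <- function(entries, gradient_length, metadata = list()) {
  stopifnot(gradient_length > 0)
  keys <- vapply(entries, function(e) paste(e$sequence, e$charge, sep = "/"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (sequence, charge) keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  rts <- vapply(entries, `[[`, numeric(1), "retention_time")
  if (length(rts) && any(rts < 0 | rts > gradient_length))
    stop("retention times outside the 0-", gradient_length, " min gradient")
  structure(list(entries = entries,
                 gradient_length = as.numeric(gradient_length),
                 metadata = metadata),
            class = "chrom_library")
}

#' @export
print.chrom_library <- function(x, ...) {
  n_tr <- sum(vapply(x$entries, function(e) length(e$transitions), integer(1)))
  cat("chrom_library:", length(x$entries), "precursors,", n_tr,
      "transitions,", x$gradient_length, "min gradient\n")
  invisible(x)
}

#' @export
length.chrom_library <- function(x) length(x$entries)

.lib_keys <- function(lib) {
  vapply(lib$entries, function(e) paste(e$sequence, e$charge, sep = "/"),
         character(1))
}

.join_num <- function(x) paste(formatC(x, format = "g", digits = 15),
                               collapse = ";")
.split_num <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

.LIB_COLS <- c("peptide_sequence", "charge", "precursor_mz", "protein_ids",
               "retention_time", "score", "fragment_mz", "ion_label",
               "peak_apex", "peak_start", "peak_end")

#' Write a chromatogram library as a delimited table
#'
#' The canonical `arrays` dialect is one row per transition with times and
#' intensities as semicolon-joined numeric strings; the `long_table` dialect
#' is one row per transition time point with plain `time` / `intensity`
#' columns. Both round-trip losslessly through [read_library()] (the
#' long_table dialect drops nothing because peak metadata is repeated per
#' row).
#'
#' @param lib a [chrom_library()].
#' @param path output file path.
#' @param dialect `"arrays"` (default) or `"long_table"`.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, dialect = c("arrays", "long_table"),
                          sep = "\t") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(lib, "chrom_library"))
  rows <- list()
  for (e in lib$entries) {
    pk <- e$peak
    for (tr in e$transitions) {
      base <- data.frame(
        peptide_sequence = e$sequence, charge = e$charge,
        precursor_mz = e$precursor_mz,
        protein_ids = paste(e$protein_ids, collapse = ";"),
        retention_time = e$retention_time, score = e$score,
        fragment_mz = tr$fragment_mz, ion_label = tr$ion_label,
        peak_apex = if (is.null(pk)) NA_real_ else pk$apex_time,
        peak_start = if (is.null(pk)) NA_real_ else pk$boundary_start,
        peak_end = if (is.null(pk)) NA_real_ else pk$boundary_end,
        stringsAsFactors = FALSE)
      if (dialect == "arrays") {
        base$times <- .join_num(tr$times)
        base$intensities <- .join_num(tr$intensities)
        rows[[length(rows) + 1L]] <- base
      } else {
        long <- base[rep(1L, length(tr$times)), , drop = FALSE]
        long$time <- tr$times
        long$intensity <- tr$intensities
        rows[[length(rows) + 1L]] <- long
      }
    }
  }
  hdr_cols <- c(.LIB_COLS,
                if (dialect == "arrays") c("times", "intensities")
                else c("time", "intensity"))
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(hdr_cols)),
                           hdr_cols), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# prmflow chromatogram library; dialect=", dialect,
                    "; gradient_length=", lib$gradient_length), con)
  for (k in names(lib$metadata))
    writeLines(paste0("# meta:", k, "=", lib$metadata[[k]]), con)
  write.table(tab[, hdr_cols], con, sep = sep, quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a chromatogram library from a delimited table
#'
#' @param path input file (see [write_library()] for the two dialects).
#' @param dialect `"arrays"`, `"long_table"`, or `"auto"` (default; sniffed
#'   from the header comment or the column set).
#' @param sep field separator.
#' @param gradient_length override for the gradient length when the file
#'   header does not record one.
#' @return a [chrom_library()].
#' @export
read_library <- function(path, dialect = c("auto", "arrays", "long_table"),
                         sep = "\t", gradient_length = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 50L)
  meta <- list()
  glen <- gradient_length
  for (ln in hdr[startsWith(hdr, "#")]) {
    m <- regmatches(ln, regexec("gradient_length=([0-9.eE+-]+)", ln))[[1]]
    if (length(m) == 2L) glen <- as.numeric(m[2])
    mm <- regmatches(ln, regexec("^# meta:([^=]+)=(.*)$", ln))[[1]]
    if (length(mm) == 3L) meta[[mm[2]]] <- mm[3]
    md <- regmatches(ln, regexec("dialect=([a-z_]+)", ln))[[1]]
    if (length(md) == 2L && dialect == "auto") dialect <- md[2]
  }
  tab <- read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "auto")
    dialect <- if ("times" %in% names(tab)) "arrays" else "long_table"
  need <- c(.LIB_COLS, if (dialect == "arrays") c("times", "intensities")
            else c("time", "intensity"))
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("library table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) {
    if (is.null(glen)) glen <- 1
    return(chrom_library(list(), glen, meta))
  }
  if (dialect == "long_table") {
    # collapse time points back into array rows, preserving input order
    grp <- paste(tab$peptide_sequence, tab$charge, tab$fragment_mz,
                 tab$ion_label, sep = "\r")
    idx <- split(seq_len(nrow(tab)), factor(grp, levels = unique(grp)))
    tab2 <- tab[vapply(idx, `[`, integer(1), 1L), , drop = FALSE]
    tab2$times <- vapply(idx, function(i) .join_num(tab$time[i]), character(1))
    tab2$intensities <- vapply(idx, function(i) .join_num(tab$intensity[i]),
                               character(1))
    tab <- tab2
  }
  key <- paste(tab$peptide_sequence, tab$charge, sep = "/")
  entries <- list()
  for (k in unique(key)) {
    ri <- which(key == k)
    trs <- lapply(ri, function(i) {
      tryCatch(
        transition_trace(tab$fragment_mz[i], tab$ion_label[i],
                         .split_num(tab$times[i]),
                         .split_num(tab$intensities[i])),
        error = function(e) stop("row ", i, " (", k, " ", tab$ion_label[i],
                                 "): ", conditionMessage(e), call. = FALSE))
    })
    i1 <- ri[1]
    pk <- if (!is.na(tab$peak_apex[i1]) && nzchar(tab$peak_apex[i1]))
      peak_feature(as.numeric(tab$peak_apex[i1]),
                   as.numeric(tab$peak_start[i1]),
                   as.numeric(tab$peak_end[i1]),
                   area = NA_real_) else NULL
    entries[[length(entries) + 1L]] <- chrom_entry(
      sequence = tab$peptide_sequence[i1], charge = tab$charge[i1],
      protein_ids = strsplit(as.character(tab$protein_ids[i1]), ";")[[1]],
      retention_time = tab$retention_time[i1],
      transitions = trs,
      precursor_mz = tab$precursor_mz[i1],
      peak = pk,
      score = suppressWarnings(as.numeric(tab$score[i1])))
  }
  if (is.null(glen))
    glen <- max(vapply(entries, `[[`, numeric(1), "retention_time")) + 1
  chrom_library(entries, glen, meta)
}

#' Restrict a library to assay-suitable, protein-unique peptides
#'
#' Applies the bookkeeping used when turning a survey library into an assay
#' panel: drop explicitly excluded peptides (e.g. those shared with the
#' background-matrix species), resolve protein mapping by greedy set-cover
#' parsimony and keep only peptides unique to a single selected protein, and
#' drop missed-cleavage peptides unless their protein is whitelisted (the
#' case where missed-cleavage peptides are the only unique ones, as for
#' PRDX2).
#'
#' @param lib a [chrom_library()].
#' @param proteome proteome map (named character vector).
#' @param exclusions peptide sequences to remove outright.
#' @param keep_missed_cleavage_proteins accessions whose missed-cleavage
#'   peptides are retained.
#' @param missed_cleavages digestion depth used to index the proteome.
#' @return filtered [chrom_library()]; attribute `"n_unmatched"` counts
#'   entries dropped because their peptide was absent from the proteome.
#' @export
filter_unique_peptides <- function(lib, proteome, exclusions = character(0),
                                   keep_missed_cleavage_proteins = character(0),
                                   missed_cleavages = 2L) {
  validate_proteome(proteome)
  pep2prot <- new.env(parent = emptyenv())
  for (acc in sort(names(proteome))) {
    for (p in unique(digest(proteome[[acc]], missed_cleavages)))
      assign(p, c(if (exists(p, pep2prot)) get(p, pep2prot), acc), pep2prot)
  }
  seqs <- vapply(lib$entries, function(e) strip_modifications(e$sequence),
                 character(1))
  keep <- !(seqs %in% exclusions)
  matched <- vapply(seqs, exists, logical(1), envir = pep2prot)
  n_unmatched <- sum(keep & !matched)
  if (n_unmatched > 0)
    warning(n_unmatched, " library peptide(s) absent from the proteome; dropped")
  keep <- keep & matched
  # greedy set-cover parsimony over the remaining peptides
  pep_set <- unique(seqs[keep])
  prot_peps <- list()
  for (p in pep_set)
    for (acc in get(p, pep2prot))
      prot_peps[[acc]] <- c(prot_peps[[acc]], p)
  selected <- character(0)
  uncovered <- pep_set
  while (length(uncovered)) {
    gain <- vapply(prot_peps, function(pp) length(intersect(pp, uncovered)),
                   integer(1))
    gain <- gain[gain > 0]
    if (!length(gain)) break
    best <- sort(names(gain)[gain == max(gain)])[1]
    selected <- c(selected, best)
    uncovered <- setdiff(uncovered, prot_peps[[best]])
  }
  out <- list()
  for (i in seq_along(lib$entries)) {
    if (!keep[i]) next
    e <- lib$entries[[i]]
    owners <- intersect(get(seqs[i], pep2prot), selected)
    if (length(owners) != 1L) next
    if (missed_cleavage_count(e$sequence) > 0 &&
        !owners %in% keep_missed_cleavage_proteins) next
    e$protein_ids <- owners
    out[[length(out) + 1L]] <- e
  }
  res <- chrom_library(out, lib$gradient_length, lib$metadata)
  attr(res, "n_unmatched") <- n_unmatched
  res
}
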