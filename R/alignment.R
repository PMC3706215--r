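# Gapped protein alignment container and FASTA IO.
#
# Column coordinates are 0-based, half-open everywhere inside the package;
# report files print 1-based inclusive spans (see write_indel_report).

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a gapped protein alignment
#'
#' An alignment holds two or more equal-length gapped amino-acid strings,
#' keyed by unique sequence IDs, together with a map from sequence ID to
#' taxon ID.  The alphabet is the 20 amino acids, `X` (unknown residue,
#' never counted as a consensus residue) and the gap character `-`.
#' The characters `.` and `*` are rejected: their meaning differs between
#' alignment programs and silently reinterpreting them invites column
#' miscounts.
#'
#' @param records Named character vector of gapped sequences (mixed case
#'   accepted; stored upper case).
#' @param taxon_of Optional named character vector mapping sequence IDs to
#'   taxon IDs.  Defaults to the identity map (sequence ID = taxon ID).
#' @return An object of class `aa_alignment` with elements `records`,
#'   `taxon_of` and `length` (number of columns).
#' @examples
#' aln <- alignment(c(s1 = "MK-LV", s2 = "MKALV"))
#' aln$length
#' @export
alignment <- function(records, taxon_of = NULL) {
  records <- unlist(records)
  if (length(records) < 2L)
    stop("an alignment needs at least 2 sequences, got ", length(records))
  ids <- names(records)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all alignment records must carry a sequence ID")
  if (anyDuplicated(ids))
    stop("duplicate sequence IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- toupper(records)
  lens <- nchar(records)
  if (length(unique(lens)) != 1L) {
    ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
    bad <- ids[lens != ref]
    stop("ragged alignment: record(s) ", paste(bad, collapse = ", "),
         " differ in length from the majority length ", ref)
  }
  len <- lens[[1L]]
  if (len < 1L) stop("alignment has zero columns")
  if (any(grepl("[.*]", records, fixed = FALSE)))
    stop("characters '.' and '*' are not accepted in aligned sequences; ",
         "replace them explicitly before import")
  bad <- grepl(sprintf("[^%sX-]", paste(AA_CODES, collapse = "")), records)
  if (any(bad))
    stop("record(s) ", paste(ids[bad], collapse = ", "),
         " contain characters outside the amino-acid alphabet, 'X' and '-'")
  if (is.null(taxon_of)) {
    taxon_of <- stats::setNames(ids, ids)
  } else {
    taxon_of <- unlist(taxon_of)
    if (!all(ids %in% names(taxon_of)))
      stop("taxon_of lacks entries for: ",
           paste(setdiff(ids, names(taxon_of)), collapse = ", "))
    taxon_of <- taxon_of[ids]
  }
  structure(list(records = records, taxon_of = taxon_of, length = len),
            class = "aa_alignment")
}

# character matrix view: one row per sequence, one column per alignment column
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$records, "", fixed = TRUE))
  rownames(m) <- names(aln$records)
  m
}

#' Ungapped residue counts of an alignment's sequences
#' @param aln An `aa_alignment`.
#' @return Named integer vector of residue counts (gaps excluded).
#' @export
ungapped_lengths <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  nchar(gsub("-", "", aln$records, fixed = TRUE))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Protein alignment: ", length(x$records), " sequences x ",
      x$length, " columns\n", sep = "")
  ug <- ungapped_lengths(x)
  cat("  ungapped lengths ", min(ug), "-", max(ug),
      " (mean ", round(mean(ug), 1), ")\n", sep = "")
  show <- utils::head(names(x$records), 5L)
  cat("  sequences: ", paste(show, collapse = ", "),
      if (length(x$records) > 5L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' Accepts arbitrary line wrapping and mixed case; the gap character is
#' `-`.  Ragged records, empty files and the ambiguous characters `.`/`*`
#' are hard errors.
#'
#' @param path Path to an aligned FASTA file.
#' @param taxon_of Optional sequence-ID to taxon-ID map (see [alignment()]).
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, taxon_of = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  recs <- as.character(set)
  # FASTA descriptions: keep the first whitespace-delimited word as the ID
  names(recs) <- sub("\\s.*$", "", names(recs))
  alignment(recs, taxon_of = taxon_of)
}

#' Write an alignment to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  set <- Biostrings::BStringSet(aln$records)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
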