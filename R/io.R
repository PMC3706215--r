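# Readers/writers for the remaining formats: newick reference trees,
# taxon rosters, BLAST tabular hit files and the indel report TSV.

#' Read a rooted reference phylogeny from newick
#'
#' Leaf labels must be unique; polytomies are allowed.  A warning is
#' issued for unrooted trees (the classification stage treats the
#' single-event test in a rooting-invariant way, but clade and ambiguity
#' reporting follow the rooting as given).
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable newick in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable newick in ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tr))
    warning("tree in ", path, " is unrooted; treating the basal ",
            "polytomy as the root")
  tr
}

#' Read a taxon roster table
#'
#' A tab-separated table with a header and at least the columns `taxon`
#' and `group` (major group label, e.g. Metazoa/Fungi/Viridiplantae).
#' An optional logical column `deep` flags taxa that are the sole
#' representative of a deep branch; these drive the alignment-coverage
#' categories.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `taxon_roster`.
#' @export
read_taxon_roster <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxon_roster(df)
}

#' Construct a taxon roster
#' @param df Data frame with columns `taxon`, `group` and optionally `deep`.
#' @return The validated roster (class `taxon_roster`).
#' @export
taxon_roster <- function(df) {
  if (!all(c("taxon", "group") %in% names(df)))
    stop("a taxon roster needs columns 'taxon' and 'group'")
  if (anyDuplicated(df$taxon))
    stop("duplicate taxa in roster: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  if (is.null(df$deep)) df$deep <- FALSE
  df$deep <- as.logical(df$deep)
  class(df) <- c("taxon_roster", "data.frame")
  df
}

deep_taxa_of <- function(roster) roster$taxon[roster$deep %in% TRUE]

#' Read a tabular BLAST hit file
#'
#' Accepts either a minimal three-column table (`qseqid`, `sseqid`,
#' `evalue`) or standard 12-column `-outfmt 6` output (E-value in column
#' 11).  A header row is detected and skipped if present.
#'
#' @param path Path to the tab-separated hit file.
#' @return Data frame with columns `qseqid`, `sseqid`, `evalue`.
#' @export
read_blast_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty BLAST table: ", path)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  header <- any(tolower(fields) %in% c("qseqid", "sseqid", "evalue"))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (header) {
    names(df) <- tolower(names(df))
    need <- c("qseqid", "sseqid", "evalue")
    if (!all(need %in% names(df)))
      stop("BLAST table header lacks columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    df <- df[need]
  } else if (ncol(df) >= 11L) {
    df <- df[c(1L, 2L, 11L)]
    names(df) <- c("qseqid", "sseqid", "evalue")
  } else if (ncol(df) >= 3L) {
    df <- df[1:3]
    names(df) <- c("qseqid", "sseqid", "evalue")
  } else {
    stop("BLAST table needs at least 3 columns (qseqid, sseqid, evalue)")
  }
  df$evalue <- as.numeric(df$evalue)
  if (anyNA(df$evalue)) stop("non-numeric E-values in ", path)
  df
}

#' Write an indel report TSV
#'
#' One row per indel region.  Internally spans are 0-based half-open;
#' the report prints the bioinformatics convention of 1-based inclusive
#' `start`/`end` columns.  The `bearing_taxa` field is a comma-joined
#' list.
#'
#' @param records An `indel_set` (see [extract_indels()]), optionally
#'   augmented with the call columns `type` and `polarity` as produced by
#'   [classify_events()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_indel_report()]
#' @export
write_indel_report <- function(records, path) {
  cols <- c("cluster", "start", "end", "width", "n_states", "kind",
            "length", "type", "polarity", "bearing_taxa")
  df <- as.data.frame(records)
  n <- nrow(df)
  out <- data.frame(cluster = character(n), stringsAsFactors = FALSE)
  out$cluster <- if (is.null(df$cluster)) rep(NA_character_, n) else df$cluster
  out$start <- if (n) df$start + 1L else integer(0)  # 1-based inclusive
  out$end <- df$end                                  # half-open -> inclusive
  out$width <- df$width
  out$n_states <- df$n_states
  out$kind <- df$kind
  out$length <- if (is.null(df$length)) rep(NA_integer_, n) else df$length
  out$type <- if (is.null(df$type)) rep(NA_character_, n) else df$type
  out$polarity <- if (is.null(df$polarity)) rep(NA_character_, n) else df$polarity
  bt <- df$bearing_taxa
  out$bearing_taxa <- if (is.null(bt)) rep(NA_character_, n) else
    vapply(bt, function(x) paste(x, collapse = ","), "")
  out <- out[cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Re-read an indel report TSV
#'
#' Restores internal 0-based half-open spans and splits `bearing_taxa`
#' back into character vectors.
#'
#' @param path Path written by [write_indel_report()].
#' @return A data frame mirroring the serialized fields.
#' @export
read_indel_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df$start <- df$start - 1L          # back to 0-based half-open
  df$cluster <- as.character(df$cluster)
  df$bearing_taxa <- I(lapply(df$bearing_taxa, function(x) {
    if (is.na(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1L]]
  }))
  df
}
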