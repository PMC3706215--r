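# Consensus-guided indel extraction: conservation profile, region
# delimitation, simple/complex state classification, threshold survey.

# Per-column consensus statistics, computed once per alignment and shared
# by every threshold.  The consensus fraction of a column is
#   100 * (count of the most frequent residue) / (number of sequences),
# with gaps counted in the denominator and neither '-' nor 'X' ever
# eligible as the consensus residue.  When residues tie for most
# frequent, the tied maximum count defines the fraction and the
# alphabetically first residue is reported as the consensus identity.
consensus_stats <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  L <- ncol(m)
  codes <- match(m, AA_CODES)        # gaps and 'X' become NA
  dim(codes) <- dim(m)
  maxc <- integer(L)
  cons <- rep(NA_character_, L)
  for (j in seq_len(L)) {
    tb <- tabulate(codes[, j], nbins = 20L)
    mc <- max(tb)
    maxc[j] <- mc
    if (mc > 0L) cons[j] <- AA_CODES[which.max(tb)]
  }
  list(fraction = 100 * maxc / n,
       consensus = cons,
       any_gap = colSums(m == "-") > 0L,
       matrix = m)
}

#' Build a per-column conservation profile
#'
#' A column is conserved at a similarity threshold `t` (percent) when at
#' least `t`% of the sequences share its most frequent residue, gaps
#' counting in the denominator and never as the consensus.  `X` matches
#' nothing.  The profile is deterministic given the alignment and
#' threshold.
#'
#' @param aln An `aa_alignment`.
#' @param threshold Similarity threshold in percent, in \[25, 100\].
#' @return Object of class `conservation_profile`: list with `threshold`,
#'   logical `flags` (conserved/variable per column), the raw `fraction`
#'   per column, the consensus residue per column and an `any_gap` flag
#'   per column.
#' @examples
#' aln <- alignment(c(a = "AAC", b = "AAC", c = "A-C", d = "T-C"))
#' build_conservation_profile(aln, 50)$flags
#' @export
build_conservation_profile <- function(aln, threshold) {
  stopifnot(inherits(aln, "aa_alignment"),
            threshold >= 25, threshold <= 100)
  st <- consensus_stats(aln)
  structure(list(threshold = threshold,
                 flags = st$fraction >= threshold,
                 fraction = st$fraction,
                 consensus = st$consensus,
                 any_gap = st$any_gap),
            class = "conservation_profile")
}

# Region delimitation on a logical conserved-flag vector.  Returns a
# two-column integer matrix of 0-based half-open spans.
delimit_regions <- function(flags, any_gap, inter_indel_space = 3L) {
  cons <- which(flags)
  empty <- cbind(start = integer(0), end = integer(0))
  if (length(cons) == 0L) return(empty)
  lo <- min(cons); hi <- max(cons)            # 1-based column indices
  if (hi - lo < 2L) return(empty)
  inner <- flags[lo:hi]
  r <- rle(!inner)                            # TRUE runs = variable runs
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vi <- which(r$values)
  if (length(vi) == 0L) return(empty)
  # candidate runs in full 1-based coordinates
  rs <- starts[vi] + lo - 1L
  re <- ends[vi] + lo - 1L
  # merge runs separated by fewer than inter_indel_space conserved columns;
  # the merged span keeps the intervening conserved columns
  ms <- rs[1L]; me <- re[1L]
  out_s <- integer(0); out_e <- integer(0)
  if (length(rs) > 1L) {
    for (k in 2L:length(rs)) {
      if (rs[k] - me - 1L < inter_indel_space) {
        me <- re[k]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- rs[k]; me <- re[k]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  # only spans in which at least one sequence has a gap
  has_gap <- vapply(seq_along(out_s),
                    function(k) any(any_gap[out_s[k]:out_e[k]]), logical(1))
  cbind(start = out_s[has_gap] - 1L, end = out_e[has_gap])  # 0-based half-open
}

#' Identify candidate indel regions from a conservation profile
#'
#' Maximal runs of variable columns are candidate regions; two candidates
#' separated by fewer than `inter_indel_space` conserved columns are
#' merged, the merged span keeping the intervening conserved columns.
#' Alignment ends before the first and after the last conserved column
#' are excluded (no conserved anchor), and only spans in which at least
#' one sequence has a gap are returned.
#'
#' @param profile A `conservation_profile`.
#' @param inter_indel_space Minimum number of conserved columns keeping
#'   two regions separate (default 3).
#' @return Integer matrix with columns `start`, `end`: 0-based half-open
#'   column spans, sorted by start.
#' @export
identify_indel_regions <- function(profile, inter_indel_space = 3L) {
  stopifnot(inherits(profile, "conservation_profile"),
            inter_indel_space >= 1L)
  delimit_regions(profile$flags, profile$any_gap, inter_indel_space)
}

# Terminal gap runs: leading/trailing gap stretches per sequence are
# missing data (fragmentary ends), not deletion events.
terminal_gap_runs <- function(aln) {
  lead <- nchar(sub("[^-].*$", "", aln$records))
  trail <- nchar(sub("^.*[^-]", "", aln$records))
  all_gap <- !grepl("[^-]", aln$records)
  lead[all_gap] <- aln$length
  trail[all_gap] <- 0L
  cbind(lead = lead, trail = trail)
}

#' Classify one indel region as simple or complex
#'
#' Each sequence's gap pattern over the span is reduced to a mask
#' (`R` = residue, `-` = gap).  Sequences whose span lies entirely
#' inside a terminal gap run are flagged as missing data and excluded
#' from the state set.  A region is a *simple* indel when exactly two
#' states remain — segment fully present and segment fully absent — and
#' *complex* when there are more states (or two states one of which is
#' partial).  The length of a simple indel is the span width.
#'
#' @param aln An `aa_alignment`.
#' @param span Integer vector `c(start, end)`, 0-based half-open, as
#'   produced by [identify_indel_regions()].
#' @return Object of class `indel_record`: list with `start`, `end`,
#'   `width`, `masks` (named per-sequence masks), `missing` (sequence IDs
#'   treated as missing data), `states`, `n_states`, `kind`
#'   (`"simple"`/`"complex"`) and `length` (simple only, else `NA`).
#' @export
classify_indel <- function(aln, span) {
  stopifnot(inherits(aln, "aa_alignment"), length(span) == 2L)
  start <- as.integer(span[[1L]]); end <- as.integer(span[[2L]])
  if (start < 0L || end > aln$length || end <= start)
    stop("span [", start, ",", end, ") outside alignment columns")
  seg <- substr(aln$records, start + 1L, end)
  masks <- chartr(paste(c(AA_CODES, "X"), collapse = ""),
                  strrep("R", 21L), seg)
  tg <- terminal_gap_runs(aln)
  missing <- names(aln$records)[end <= tg[, "lead"] |
                                start >= aln$length - tg[, "trail"]]
  scored <- setdiff(names(aln$records), missing)
  states <- unique(masks[scored])
  if (length(states) < 2L)
    stop(no_indel_error(start, end, length(states)))
  width <- end - start
  full <- strrep("R", width)
  gap <- strrep("-", width)
  simple <- length(states) == 2L && all(c(full, gap) %in% states)
  structure(list(start = start, end = end, width = width,
                 masks = masks, missing = missing,
                 states = states, n_states = length(states),
                 kind = if (simple) "simple" else "complex",
                 length = if (simple) width else NA_integer_),
            class = "indel_record")
}

no_indel_error <- function(start, end, n_states) {
  structure(class = c("no_indel_error", "error", "condition"),
            list(message = sprintf(
              "span [%d,%d) has %d distinct state(s) after excluding missing data: not an indel",
              start, end, n_states), call = NULL))
}

# shared worker: regions + per-region classification from cached stats
extract_with_stats <- function(aln, st, threshold, inter_indel_space,
                               cluster = NA_character_) {
  flags <- st$fraction >= threshold
  spans <- delimit_regions(flags, st$any_gap, inter_indel_space)
  recs <- vector("list", nrow(spans))
  keep <- logical(nrow(spans))
  for (k in seq_len(nrow(spans))) {
    r <- tryCatch(classify_indel(aln, spans[k, ]),
                  no_indel_error = function(e) NULL)
    if (!is.null(r)) { recs[[k]] <- r; keep[k] <- TRUE }
  }
  recs <- recs[keep]
  df <- data.frame(
    cluster = rep(cluster, length(recs)),
    start = vapply(recs, `[[`, 0L, "start"),
    end = vapply(recs, `[[`, 0L, "end"),
    width = vapply(recs, `[[`, 0L, "width"),
    n_states = vapply(recs, `[[`, 0L, "n_states"),
    kind = vapply(recs, `[[`, "", "kind"),
    length = vapply(recs, `[[`, NA_integer_, "length"),
    stringsAsFactors = FALSE)
  df$masks <- I(lapply(recs, `[[`, "masks"))
  df$missing <- I(lapply(recs, `[[`, "missing"))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("indel_set", "data.frame")
  df
}

#' Extract and classify all indel regions of an alignment
#'
#' Composition of [build_conservation_profile()],
#' [identify_indel_regions()] and [classify_indel()].  Regions that
#' collapse to a single state once missing-data sequences are excluded
#' (gaps confined to fragmentary ends) are dropped.  Output is sorted by
#' span start and fully deterministic.
#'
#' @param aln An `aa_alignment`.
#' @param threshold Similarity threshold percent (default 50).
#' @param inter_indel_space Merge distance in conserved columns (default 3).
#' @param cluster Optional cluster ID stamped on every record.
#' @return An `indel_set`: data frame with columns `cluster`, `start`,
#'   `end`, `width`, `n_states`, `kind`, `length` and list columns
#'   `masks`, `missing`.
#' @export
extract_indels <- function(aln, threshold = 50, inter_indel_space = 3L,
                           cluster = NA_character_) {
  stopifnot(inherits(aln, "aa_alignment"),
            threshold >= 25, threshold <= 100)
  st <- consensus_stats(aln)
  extract_with_stats(aln, st, threshold, inter_indel_space, cluster)
}

#' Survey indel counts across similarity thresholds
#'
#' Runs the extraction at every threshold on a grid (default 25 to 100
#' in steps of 5) over a set of alignments and totals simple and complex
#' indels per threshold.
#'
#' @param alignments List of `aa_alignment` objects (at least one).
#' @param lo,hi,step Threshold grid in percent.
#' @param inter_indel_space Merge distance (default 3).
#' @return Data frame of class `threshold_survey` with columns
#'   `threshold`, `n_simple`, `n_complex`.
#' @export
threshold_survey <- function(alignments, lo = 25, hi = 100, step = 5,
                             inter_indel_space = 3L) {
  if (inherits(alignments, "aa_alignment")) alignments <- list(alignments)
  if (length(alignments) == 0L) stop("no alignments to survey")
  grid <- seq(lo, hi, by = step)
  stats <- lapply(alignments, consensus_stats)
  n_simple <- n_complex <- integer(length(grid))
  for (i in seq_along(grid)) {
    for (j in seq_along(alignments)) {
      idx <- extract_with_stats(alignments[[j]], stats[[j]], grid[i],
                                inter_indel_space)
      n_simple[i] <- n_simple[i] + sum(idx$kind == "simple")
      n_complex[i] <- n_complex[i] + sum(idx$kind == "complex")
    }
  }
  structure(data.frame(threshold = grid, n_simple = n_simple,
                       n_complex = n_complex),
            class = c("threshold_survey", "data.frame"))
}

#' Pick the optimum similarity threshold from a survey
#'
#' Returns the threshold maximizing the number of complex indels (the
#' peak of the complex-count curve); ties break toward the lower
#' threshold.
#'
#' @param survey A `threshold_survey`.
#' @return The selected threshold (percent).
#' @export
select_optimal_threshold <- function(survey) {
  stopifnot(is.data.frame(survey),
            all(c("threshold", "n_complex") %in% names(survey)),
            nrow(survey) > 0L)
  if (all(survey$n_simple + survey$n_complex == 0))
    stop("no indels found at any threshold")
  survey <- survey[order(survey$threshold), , drop = FALSE]
  survey$threshold[which.max(survey$n_complex)]
}
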