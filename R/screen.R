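# Ortholog-cluster screening: BLAST hit filtering, fragment removal,
# in-paralog pruning and taxon-coverage categories.

#' Filter BLAST hits for one ortholog cluster
#'
#' Implements the three-tier hit-retention rule used when expanding seed
#' ortholog clusters across proteomes:
#'
#' 1. If any hit has E-value exactly 0.0, exactly those hits are kept
#'    (category `highly` conserved).
#' 2. Otherwise, if any hit has E-value below `e_mid`, all such hits are
#'    ranked by their log10 E-value distance to the top hit,
#'    \eqn{d_x = |log10 E_x - log10 E_1|}; the median of these distances
#'    is the cutoff and hits on the chosen side of it are retained
#'    (category `moderately`).
#' 3. Otherwise, if any hit has E-value below `e_floor`, only the single
#'    best hit is kept (category `poorly`).
#' 4. Otherwise nothing is retained (category `none`).
#'
#' The E-value distance is taken in log10 space: that is the only scale
#' on which a median over E-value gaps spanning tens of orders of
#' magnitude is meaningful.  With `keep = "near"` (default) hits with
#' `d <= cutoff` — those comparable to the best hit — are retained,
#' which is the behaviour an orthology screen wants.  `keep = "far"`
#' retains `d > cutoff` instead.
#'
#' @param hits Data frame with at least columns `sseqid` and `evalue`
#'   (a `qseqid` column is ignored; call once per query/cluster).
#' @param e_mid Moderate-tier threshold (default 1e-65).
#' @param e_floor Poor-tier threshold (default 1e-30).
#' @param keep Cutoff direction for the moderate tier, `"near"` or `"far"`.
#' @return An object of class `hit_selection`: list with `retained`
#'   (character vector of subject IDs), `category` and `cutoff`.
#' @examples
#' h <- data.frame(sseqid = c("A", "B"), evalue = c(0, 1e-200))
#' filter_blast_hits(h)$retained  # "A"
#' @export
filter_blast_hits <- function(hits, e_mid = 1e-65, e_floor = 1e-30,
                              keep = c("near", "far")) {
  keep <- match.arg(keep)
  stopifnot(is.data.frame(hits), all(c("sseqid", "evalue") %in% names(hits)))
  if (any(hits$evalue < 0)) stop("negative E-values are invalid")
  hits <- hits[order(hits$evalue), , drop = FALSE]
  sel <- function(retained, category, cutoff = NA_real_)
    structure(list(retained = retained, category = category, cutoff = cutoff),
              class = "hit_selection")
  if (nrow(hits) == 0L) return(sel(character(0), "none"))
  if (any(hits$evalue == 0))
    return(sel(hits$sseqid[hits$evalue == 0], "highly"))
  mid <- hits[hits$evalue < e_mid, , drop = FALSE]
  if (nrow(mid) > 0L) {
    d <- abs(log10(mid$evalue) - log10(mid$evalue[1L]))
    cutoff <- stats::median(d)
    take <- if (keep == "near") d <= cutoff else d > cutoff
    return(sel(mid$sseqid[take], "moderately", cutoff))
  }
  floor_hits <- hits[hits$evalue < e_floor, , drop = FALSE]
  if (nrow(floor_hits) > 0L)
    return(sel(floor_hits$sseqid[1L], "poorly"))
  sel(character(0), "none")
}

#' @export
print.hit_selection <- function(x, ...) {
  cat("BLAST hit selection: category '", x$category, "', ",
      length(x$retained), " hit(s) retained", sep = "")
  if (!is.na(x$cutoff))
    cat(" (median log10 distance cutoff ", signif(x$cutoff, 4), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Remove incomplete (fragment) sequences from an alignment
#'
#' Drops records whose ungapped residue count falls below `frac` times
#' the mean ungapped residue count of all records.  The mean is computed
#' once, over the full input set (single pass): surviving sequences are
#' not used to re-trigger further removals.
#'
#' @param aln An `aa_alignment`.
#' @param frac Fraction of the mean length below which a sequence is a
#'   fragment (default 0.5).
#' @return The filtered `aa_alignment`.
#' @export
drop_incomplete <- function(aln, frac = 0.5) {
  stopifnot(inherits(aln, "aa_alignment"), frac >= 0)
  ug <- ungapped_lengths(aln)
  keep <- ug >= frac * mean(ug)
  if (!any(keep)) stop("all sequences fall below the fragment threshold")
  if (sum(keep) < 2L)
    stop("fragment filter leaves fewer than 2 sequences")
  if (all(keep)) return(aln)
  alignment(aln$records[keep], taxon_of = aln$taxon_of[keep])
}

#' Prune in-paralogs from a gene tree
#'
#' In-paralogs are duplicates that arose after the relevant speciation:
#' they appear as a well-supported clade of sequences from a single
#' species.  For every maximal clade with bootstrap support above
#' `support_min` whose leaves all map to one taxon, only the leaf with
#' the shortest root-to-leaf path is kept; all other leaves are returned
#' unchanged.  The last sequence of a taxon is never removed.
#'
#' @param tree A `phylo` gene tree whose `node.label` holds bootstrap
#'   supports in \[0, 100\] (non-numeric or missing labels are treated as
#'   unsupported).
#' @param taxon_of Named character vector mapping tip labels to taxa.
#' @param support_min Support gate (default 70; clades must exceed it).
#' @return Character vector of retained tip labels, in tip order.
#' @export
prune_inparalogs <- function(tree, taxon_of, support_min = 70) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(taxon_of)))
    stop("unresolved taxon mapping for tip(s): ",
         paste(setdiff(tree$tip.label, names(taxon_of)), collapse = ", "))
  taxa <- taxon_of[tree$tip.label]
  nnode <- tree$Nnode
  supports <- rep(NA_real_, nnode)
  if (!is.null(tree$node.label))
    supports <- suppressWarnings(as.numeric(tree$node.label))
  tl <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else tree$edge.length
  tree2 <- tree
  tree2$edge.length <- tl
  depth <- ape::node.depth.edgelength(tree2)  # root-to-node distances

  idx <- tree_index(tree)
  root <- ntip + 1L
  drop <- character(0)
  visit <- function(node) {
    if (node <= ntip) return(invisible())
    tips <- idx$desc[[node]]
    supp <- supports[node - ntip]
    if (!is.na(supp) && supp > support_min &&
        length(unique(taxa[tips])) == 1L) {
      tip_ids <- match(tips, tree$tip.label)
      best <- tip_ids[which.min(depth[tip_ids])]
      drop <<- c(drop, setdiff(tips, tree$tip.label[best]))
      return(invisible())  # maximal clade: do not descend
    }
    for (ch in idx$children[[node]]) visit(ch)
    invisible()
  }
  visit(root)
  setdiff(tree$tip.label, drop)
}

#' Categorize an alignment's taxon coverage
#'
#' Alignments are binned into four quality categories from the taxa they
#' sample relative to the full roster:
#' `complete` (nothing missing); `nearly_complete` (at most 2 missing,
#' none of them a deep taxon); `patchy` (3-7 missing, all deep taxa
#' present); `flawed` (any deep taxon missing, an entire major group
#' missing, or more than 7 taxa missing).  Deep taxa are the sole
#' representatives of deep branches.  The rule table is total and
#' disjoint: exactly one label applies to any sampled set.
#'
#' @param sampled Character vector of sampled taxa.
#' @param roster A `taxon_roster`.
#' @param deep_taxa Deep-branch taxa; defaults to the roster's `deep` flag.
#' @return Object of class `alignment_category`: list with `label` and
#'   `missing`.
#' @export
categorize_alignment <- function(sampled, roster, deep_taxa = NULL) {
  stopifnot(inherits(roster, "taxon_roster"))
  full <- roster$taxon
  if (!all(sampled %in% full))
    stop("sampled taxa absent from roster: ",
         paste(setdiff(sampled, full), collapse = ", "))
  if (is.null(deep_taxa)) deep_taxa <- deep_taxa_of(roster)
  if (!all(deep_taxa %in% full))
    stop("deep taxa absent from roster: ",
         paste(setdiff(deep_taxa, full), collapse = ", "))
  missing <- setdiff(full, sampled)
  group_gone <- any(vapply(split(roster$taxon, roster$group),
                           function(g) all(g %in% missing), logical(1)))
  label <-
    if (length(missing) == 0L) "complete"
    else if (any(deep_taxa %in% missing) || group_gone ||
             length(missing) > 7L) "flawed"
    else if (length(missing) <= 2L) "nearly_complete"
    else "patchy"
  structure(list(label = label, missing = missing),
            class = "alignment_category")
}

#' @export
print.alignment_category <- function(x, ...) {
  cat("Alignment coverage: ", x$label,
      " (", length(x$missing), " taxa missing)\n", sep = "")
  invisible(x)
}
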