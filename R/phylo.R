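# Phylogenetic interpretation of simple indels: singleton / CDI /
# homoplastic / ambiguous typing, polarization, I:D ratios, and the
# associated summary statistics.

# Cached per-tree structure: children lists, parent vector and
# descendant-tip sets for every node.  Root = ntip + 1 (ape convention).
tree_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  children <- vector("list", nn)
  parent <- integer(nn)
  desc <- vector("list", nn)
  desc[seq_len(ntip)] <- as.list(tree$tip.label)
  e <- tree$edge
  for (i in seq_len(nrow(e))) {
    children[[e[i, 1L]]] <- c(children[[e[i, 1L]]], e[i, 2L])
    parent[e[i, 2L]] <- e[i, 1L]
  }
  # postorder accumulation of descendant tips
  po <- rev(order_nodes_preorder(e, ntip))
  for (nd in po) {
    if (nd > ntip)
      desc[[nd]] <- unlist(desc[children[[nd]]], use.names = FALSE)
  }
  list(ntip = ntip, tips = tree$tip.label, children = children,
       parent = parent, desc = desc, root = ntip + 1L)
}

# preorder node sequence from the edge matrix (root first)
order_nodes_preorder <- function(edge, ntip) {
  root <- ntip + 1L
  out <- integer(0)
  stack <- root
  kids <- split(edge[, 2L], edge[, 1L])
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, nd)
    k <- kids[[as.character(nd)]]
    if (!is.null(k)) stack <- c(stack, k)
  }
  out
}

# most recent common ancestor (node id) of a set of tip labels
mrca_node <- function(taxa, idx) {
  nd <- match(taxa[[1L]], idx$tips)
  while (!all(taxa %in% idx$desc[[nd]])) nd <- idx$parent[nd]
  nd
}

# Can the tip set S be a clade under some rooting, treating polytomies
# as soft?  TRUE iff every child subtree of MRCA(S) is entirely inside
# or entirely outside S (S is then a union of complete child subtrees).
clade_compatible <- function(S, idx) {
  if (length(S) <= 1L) return(TRUE)
  v <- mrca_node(S, idx)
  for (ch in idx$children[[v]]) {
    d <- idx$desc[[ch]]
    ins <- sum(d %in% S)
    if (ins != 0L && ins != length(d)) return(FALSE)
  }
  TRUE
}

# strict rooted monophyly on the tree as rooted
rooted_monophyletic <- function(S, idx) {
  if (length(S) == 1L) return(TRUE)
  v <- mrca_node(S, idx)
  length(idx$desc[[v]]) == length(S)
}

#' Test whether a presence pattern is explainable by a single event
#'
#' A binary presence/absence pattern over the leaves needs only one gain
#' or one loss when the bipartition it induces is compatible with the
#' tree: the bearing set or its complement forms a clade under some
#' rooting.  The test is rooting-invariant; polytomies are treated as
#' soft (a set equal to the union of some of a polytomy's child subtrees
#' counts as compatible).
#'
#' @param tree A `phylo` tree.
#' @param bearing Character vector of leaf labels carrying the state.
#' @return `TRUE` if one event suffices, `FALSE` if at least two
#'   independent events are required (homoplasy).
#' @export
single_event_compatible <- function(tree, bearing) {
  idx <- tree_index(tree)
  if (!all(bearing %in% idx$tips))
    stop("taxa absent from tree: ",
         paste(setdiff(bearing, idx$tips), collapse = ", "))
  other <- setdiff(idx$tips, bearing)
  if (length(bearing) == 0L || length(other) == 0L)
    stop("pattern is constant: no event to explain")
  clade_compatible(bearing, idx) || clade_compatible(other, idx)
}

# pick the clade side for a single-event pattern: prefer the side that is
# strictly monophyletic on the rooted tree; if both are (split adjacent
# to the root), the smaller side; ties go to the residue side.
pick_clade_side <- function(res, gap, idx) {
  mono_res <- clade_compatible(res, idx)
  mono_gap <- clade_compatible(gap, idx)
  strict_res <- mono_res && rooted_monophyletic(res, idx)
  strict_gap <- mono_gap && rooted_monophyletic(gap, idx)
  if (strict_res && strict_gap) {
    if (length(gap) < length(res)) gap else res
  } else if (strict_res) res
  else if (strict_gap) gap
  else if (mono_res) res
  else gap
}

#' Phylogenetically classify one simple indel
#'
#' The scored taxa are split into the residue-bearing set (mask all
#' residues) and the gap set (mask all gaps); missing-data sequences are
#' ignored.  Classification order:
#'
#' 1. *singleton* — exactly one scored taxon carries the minority state
#'    (residues: a singleton insertion; gap: a singleton deletion);
#' 2. *homoplastic* — neither the bearing set nor its complement can be
#'    a clade on the tree pruned to the scored taxa (at least two
#'    independent events under any rooting);
#' 3. *ambiguous* — the pattern fits a single event, but an unsampled
#'    roster taxon attaches inside the defined clade, or in its
#'    immediate sister lineage, on the full reference tree;
#' 4. *CDI* (clade-defining indel) otherwise.
#'
#' @param record An `indel_record` (must be simple).
#' @param aln The `aa_alignment` the record came from (provides the
#'   sequence-to-taxon map).
#' @param tree Full rooted reference `phylo` tree over the roster.
#' @param roster A `taxon_roster`.
#' @return A one-row data frame with columns `type`, `polarity`,
#'   `bearing_taxa` (list column), `clade` (list column; the defined
#'   clade's taxa for CDI/ambiguous calls) and `taxon` (the bearer, for
#'   singletons).
#' @export
classify_event <- function(record, aln, tree, roster) {
  stopifnot(inherits(record, "indel_record") || is.list(record))
  if (record$kind != "simple")
    stop("phylogenetic typing is defined for simple indels only")
  classify_core(record$masks, record$missing, record$width,
                aln$taxon_of, tree, roster)
}

classify_core <- function(masks, missing, width, taxon_of, tree, roster,
                          full_idx = NULL) {
  scored_seqs <- setdiff(names(masks), missing)
  full_mask <- strrep("R", width)
  gap_mask <- strrep("-", width)
  res_taxa <- unique(unname(taxon_of[scored_seqs[masks[scored_seqs] == full_mask]]))
  gap_taxa <- unique(unname(taxon_of[scored_seqs[masks[scored_seqs] == gap_mask]]))
  if (length(res_taxa) == 0L)
    stop("all-gap pattern: no residue-bearing taxon")
  if (length(gap_taxa) == 0L)
    stop("no gap-bearing taxon: span is not an indel")
  scored <- c(res_taxa, gap_taxa)
  if (is.null(full_idx)) full_idx <- tree_index(tree)
  if (!all(scored %in% full_idx$tips))
    stop("taxa absent from tree: ",
         paste(setdiff(scored, full_idx$tips), collapse = ", "))

  call <- function(type, polarity = "unpolarized", bearing = res_taxa,
                   clade = character(0), taxon = NA_character_) {
    out <- data.frame(type = type, polarity = polarity, taxon = taxon,
                      stringsAsFactors = FALSE)
    out$bearing_taxa <- I(list(bearing))
    out$clade <- I(list(clade))
    out
  }

  if (length(res_taxa) == 1L)
    return(call("singleton", "insertion", bearing = res_taxa,
                taxon = res_taxa))
  if (length(gap_taxa) == 1L)
    return(call("singleton", "deletion", bearing = gap_taxa,
                taxon = gap_taxa))

  pruned <- ape::keep.tip(tree, scored)
  pidx <- tree_index(pruned)
  if (!(clade_compatible(res_taxa, pidx) || clade_compatible(gap_taxa, pidx)))
    return(call("homoplastic"))

  clade <- pick_clade_side(res_taxa, gap_taxa, pidx)
  unsampled <- setdiff(roster$taxon, scored)
  unsampled <- intersect(unsampled, full_idx$tips)
  if (length(unsampled) > 0L) {
    v <- mrca_node(clade, full_idx)
    inside <- setdiff(full_idx$desc[[v]], clade)
    sisters <- character(0)
    if (v != full_idx$root) {
      p <- full_idx$parent[v]
      sisters <- setdiff(full_idx$desc[[p]], full_idx$desc[[v]])
    }
    if (any(unsampled %in% c(inside, sisters)))
      return(call("ambiguous", clade = sort(clade)))
  }
  call("CDI", clade = sort(clade))
}

#' Classify every simple indel of an indel set
#'
#' Vectorized driver over an `indel_set`; complex records are skipped
#' (phylogenetic typing is defined for simple indels).
#'
#' @param indels An `indel_set` from [extract_indels()].
#' @param aln The source `aa_alignment`.
#' @param tree Full rooted reference `phylo` tree.
#' @param roster A `taxon_roster`.
#' @return Data frame of class `indel_calls`: the simple records'
#'   columns (`cluster`, `start`, `end`, `width`, `length`) joined with
#'   `type`, `polarity`, `taxon`, `bearing_taxa`, `clade`.
#' @export
classify_events <- function(indels, aln, tree, roster) {
  stopifnot(inherits(indels, "indel_set"))
  full_idx <- tree_index(tree)
  simple <- which(indels$kind == "simple")
  rows <- lapply(simple, function(i) {
    cl <- classify_core(indels$masks[[i]], indels$missing[[i]],
                        indels$width[i], aln$taxon_of, tree, roster,
                        full_idx = full_idx)
    cbind(indels[i, c("cluster", "start", "end", "width", "length")], cl)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(0), start = integer(0), end = integer(0),
               width = integer(0), length = integer(0), type = character(0),
               polarity = character(0), taxon = character(0),
               bearing_taxa = I(list()), clade = I(list()))
  rownames(out) <- NULL
  class(out) <- c("indel_calls", "data.frame")
  out
}

#' Polarize a singleton indel into insertion or deletion
#'
#' With one bearer and at least two uniform non-bearers, parsimony
#' forces the direction: a lone segment present in one sequence while
#' all others are gapped is an insertion; a lone gap while all others
#' carry the segment is a deletion.
#'
#' @param record An `indel_record` whose pattern is a singleton.
#' @return `"insertion"`, `"deletion"`, or `"unpolarized"` (with a
#'   warning) when the non-bearing masks are not uniform.
#' @export
polarize_singleton <- function(record) {
  scored <- setdiff(names(record$masks), record$missing)
  m <- record$masks[scored]
  full <- strrep("R", record$width)
  gap <- strrep("-", record$width)
  n_full <- sum(m == full); n_gap <- sum(m == gap)
  if (n_full + n_gap != length(m)) {
    warning("non-bearing sequences are not uniform; cannot polarize")
    return("unpolarized")
  }
  if (n_full == 1L && n_gap >= 1L) return("insertion")
  if (n_gap == 1L && n_full >= 1L) return("deletion")
  stop("not a singleton pattern: ", n_full, " present / ", n_gap, " absent")
}

#' Insertion:deletion ratios of polarized singleton indels
#'
#' Tallies singleton insertions and deletions per taxon and reports the
#' per-taxon ratio, per-group and overall pooled ratios
#' (sum of insertions / sum of deletions) and the mean-of-taxa ratio
#' (arithmetic mean of per-taxon ratios over taxa with at least one
#' deletion).  A taxon ratio is `Inf` when it has insertions but no
#' deletions and `NA` when it has neither.
#'
#' @param calls An `indel_calls` data frame (or anything with columns
#'   `type`, `polarity`, `taxon`).
#' @param roster A `taxon_roster`; every roster taxon gets a row, zero
#'   counts included.
#' @return Object of class `id_ratio_table`: list with `per_taxon`,
#'   `per_group` data frames, `pooled` (insertions, deletions, ratio)
#'   and `mean_of_taxa`.
#' @export
compute_id_ratios <- function(calls, roster) {
  stopifnot(inherits(roster, "taxon_roster"))
  sing <- calls[calls$type %in% "singleton" &
                calls$polarity %in% c("insertion", "deletion"), , drop = FALSE]
  taxa <- roster$taxon
  ins <- stats::setNames(integer(length(taxa)), taxa)
  del <- ins
  if (nrow(sing)) {
    ti <- table(factor(sing$taxon[sing$polarity == "insertion"], levels = taxa))
    td <- table(factor(sing$taxon[sing$polarity == "deletion"], levels = taxa))
    ins[] <- as.integer(ti)
    del[] <- as.integer(td)
  }
  ratio <- ifelse(del > 0, ins / del, ifelse(ins > 0, Inf, NA_real_))
  per_taxon <- data.frame(taxon = taxa, group = roster$group,
                          insertions = as.integer(ins),
                          deletions = as.integer(del),
                          ratio = as.numeric(ratio),
                          stringsAsFactors = FALSE)
  groups <- split(per_taxon, per_taxon$group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    I <- sum(g$insertions); D <- sum(g$deletions)
    ok <- g$deletions > 0
    data.frame(group = g$group[1L], insertions = I, deletions = D,
               pooled_ratio = if (D > 0) I / D else
                 if (I > 0) Inf else NA_real_,
               mean_of_taxa = if (any(ok)) mean(g$ratio[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_group) <- NULL
  I <- sum(per_taxon$insertions); D <- sum(per_taxon$deletions)
  ok <- per_taxon$deletions > 0
  structure(list(per_taxon = per_taxon, per_group = per_group,
                 pooled = list(insertions = I, deletions = D,
                               ratio = if (D > 0) I / D else
                                 if (I > 0) Inf else NA_real_),
                 mean_of_taxa = if (any(ok)) mean(per_taxon$ratio[ok])
                                else NA_real_),
            class = "id_ratio_table")
}

#' @export
print.id_ratio_table <- function(x, ...) {
  cat("Singleton insertion:deletion ratios\n")
  cat("  pooled: ", x$pooled$insertions, " insertions / ",
      x$pooled$deletions, " deletions = ",
      round(x$pooled$ratio, 2), "\n", sep = "")
  cat("  mean of taxa (>=1 deletion): ", round(x$mean_of_taxa, 2),
      "\n", sep = "")
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Indel size distributions and summary statistics
#'
#' Bins indel sizes (span width) per integer size class within the
#' grouping given by `by`, and reports per-group summaries: count,
#' median size, and the fractions of indels of size 1, \eqn{\le} 5 and
#' \eqn{\le} 10 residues.
#'
#' @param x A data frame with a `width` column and the grouping column
#'   (`kind` for an `indel_set`; `type` or `polarity` for
#'   `indel_calls`).
#' @param by Name of the grouping column (default `"kind"`).
#' @return Object of class `indel_size_distribution`: list with
#'   `histogram` (size, group, n) and `summary` data frames.
#' @export
size_distribution <- function(x, by = "kind") {
  stopifnot(is.data.frame(x), "width" %in% names(x), by %in% names(x))
  x <- x[!is.na(x[[by]]), , drop = FALSE]
  if (nrow(x) == 0L)
    return(structure(list(histogram = data.frame(size = integer(0),
                                                 group = character(0),
                                                 n = integer(0)),
                          summary = data.frame()),
                     class = "indel_size_distribution"))
  tab <- as.data.frame(table(size = x$width, group = x[[by]]),
                       stringsAsFactors = FALSE)
  tab$size <- as.integer(tab$size)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3L] <- "n"
  rownames(tab) <- NULL
  summ <- do.call(rbind, lapply(split(x$width, x[[by]]), function(w) {
    data.frame(n = length(w), median = stats::median(w),
               frac_1aa = mean(w == 1),
               frac_le5 = mean(w <= 5),
               frac_le10 = mean(w <= 10))
  }))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  structure(list(histogram = tab, summary = summ),
            class = "indel_size_distribution")
}

#' @export
print.indel_size_distribution <- function(x, ...) {
  cat("Indel size distribution\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Regress indel counts on host protein length
#'
#' Ordinary least-squares fits of per-protein simple and complex indel
#' counts on mean ungapped protein length.  Proteins shorter than
#' `min_length` residues are excluded before fitting.
#'
#' @param per_protein Data frame with columns `length`, `n_simple`,
#'   `n_complex`.
#' @param min_length Exclusion threshold in residues (default 250).
#' @return Data frame with one row per indel kind: `kind`, `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
indel_count_vs_length_regression <- function(per_protein, min_length = 250) {
  stopifnot(is.data.frame(per_protein),
            all(c("length", "n_simple", "n_complex") %in% names(per_protein)))
  df <- per_protein[per_protein$length >= min_length, , drop = FALSE]
  if (nrow(df) < 3L)
    stop("need at least 3 proteins of length >= ", min_length)
  if (stats::var(df$length) == 0)
    stop("degenerate fit: protein lengths are constant")
  fit_one <- function(y, kind) {
    m <- stats::lm(y ~ length, data = df)
    data.frame(kind = kind,
               slope = unname(stats::coef(m)[2L]),
               intercept = unname(stats::coef(m)[1L]),
               r_squared = summary(m)$r.squared,
               n = nrow(df), stringsAsFactors = FALSE)
  }
  out <- rbind(fit_one(df$n_simple, "simple"),
               fit_one(df$n_complex, "complex"))
  rownames(out) <- NULL
  out
}

#' Per-group conservation against the consensus
#'
#' Over all columns conserved at `consensus_threshold` in the whole
#' alignment (the universally aligned consensus positions), computes for
#' each major group the percentage of those columns at which *all* of
#' the group's sequences match the consensus residue (a gap or `X`
#' counts as a mismatch).  Counts are pooled over alignments; a group's
#' denominator only includes alignments in which it has sequences.
#'
#' @param alignments List of `aa_alignment` objects.
#' @param roster A `taxon_roster`.
#' @param consensus_threshold Similarity threshold percent (default 70).
#' @return Data frame with columns `group`, `n_columns`, `n_matches`,
#'   `pct_conserved` (NA for groups with no sequences anywhere).
#' @export
group_conservation <- function(alignments, roster, consensus_threshold = 70) {
  if (inherits(alignments, "aa_alignment")) alignments <- list(alignments)
  stopifnot(inherits(roster, "taxon_roster"), length(alignments) > 0L)
  groups <- unique(roster$group)
  ncols <- stats::setNames(numeric(length(groups)), groups)
  nmatch <- ncols
  for (aln in alignments) {
    st <- consensus_stats(aln)
    keep <- st$fraction >= consensus_threshold & !is.na(st$consensus)
    if (!any(keep)) next
    m <- st$matrix[, keep, drop = FALSE]
    cons <- st$consensus[keep]
    taxa <- aln$taxon_of[rownames(m)]
    grp <- roster$group[match(taxa, roster$taxon)]
    for (g in groups) {
      rows <- which(grp %in% g)
      if (length(rows) == 0L) next
      sub <- m[rows, , drop = FALSE]
      ok <- colSums(sub == matrix(cons, nrow = length(rows),
                                  ncol = ncol(sub), byrow = TRUE)) ==
        length(rows)
      ncols[g] <- ncols[g] + ncol(sub)
      nmatch[g] <- nmatch[g] + sum(ok)
    }
  }
  data.frame(group = groups,
             n_columns = as.integer(ncols),
             n_matches = as.integer(nmatch),
             pct_conserved = ifelse(ncols > 0, 100 * nmatch / ncols, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}
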