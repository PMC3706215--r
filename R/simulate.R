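# Synthetic corpus generator: plants insertion/deletion events on the
# branches of a reference phylogeny and emits alignments whose indel
# regions are recoverable exactly, together with a ground-truth event log.

#' Bundled synthetic 35-taxon reference tree
#'
#' A rooted tree over 35 taxa mirroring a broad eukaryote sampling
#' (15 Metazoa, 8 Fungi, 8 Viridiplantae, 2 Amoebozoa, 1 Rhodophyta,
#' 1 Choanoflagellata) with uniform branch lengths.  It is a synthetic
#' stand-in constructed for simulation and examples, not a published
#' phylogeny.
#'
#' @return A `phylo` tree.
#' @export
example_tree <- function() {
  read_tree(system.file("extdata", "synthetic_tree.nwk",
                        package = "indelatlas", mustWork = TRUE))
}

#' Bundled synthetic taxon roster
#'
#' Roster matching [example_tree()]: major-group labels and the three
#' sole-representative deep-branch taxa (the red alga, the
#' choanoflagellate and the chytrid).
#'
#' @return A `taxon_roster`.
#' @export
example_roster <- function() {
  read_taxon_roster(system.file("extdata", "synthetic_roster.tsv",
                                package = "indelatlas", mustWork = TRUE))
}

#' Simulation configuration
#'
#' Defines the data-generating conditions of the synthetic corpus:
#' insertion and deletion events arise on branches as a Poisson process
#' with per-site, per-unit-branch-length rates, event lengths follow a
#' 1aa-heavy geometric law, and events are separated by conserved flanks
#' of identical residues so that extraction can recover them exactly.
#'
#' Defaults: deletion rate 1.4e-3 with insertions 2.31 times as
#' frequent (the insertion bias observed in universal single-copy
#' eukaryotic proteins), geometric length parameter 0.427 (so ~43% of
#' events are 1aa), proteins of 250-1000 residues, flank width 5.
#'
#' @param tree Reference `phylo` tree with branch lengths.
#' @param roster Matching `taxon_roster`.
#' @param n_proteins Number of proteins (alignments) to simulate.
#' @param length_range Protein length range in residues (min 250).
#' @param ins_rate,del_rate Events per site per unit branch length.
#' @param size_p Geometric parameter for event lengths; `P(len = 1) = size_p`.
#' @param flank Conserved flank width in columns; must be at least
#'   `inter_indel_space` so planted regions never merge.
#' @param inter_indel_space Extraction merge distance the corpus is
#'   built for (default 3).
#' @param noise_rate Per-site rate of substitution-noise columns; noise
#'   columns are gap-free, placed in their own flanked slots so recovery
#'   guarantees are preserved.
#' @param complex_fraction Probability that an insertion region of
#'   width >= 3 on an internal branch receives a nested deletion on a
#'   descendant branch, yielding a multi-state (complex) region.
#' @param terminal_only If `TRUE`, events are placed on terminal
#'   branches only (every simple region is then a singleton).
#' @param seed Integer seed; a fixed seed makes the corpus bit-identical.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(tree = example_tree(),
                              roster = example_roster(),
                              n_proteins = 100,
                              length_range = c(250, 1000),
                              ins_rate = 2.31 * 1.4e-3,
                              del_rate = 1.4e-3,
                              size_p = 0.427,
                              flank = 5L,
                              inter_indel_space = 3L,
                              noise_rate = 0,
                              complex_fraction = 0.2,
                              terminal_only = FALSE,
                              seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(roster, "taxon_roster"),
            n_proteins >= 1, length(length_range) == 2L,
            length_range[1] >= 250, length_range[2] >= length_range[1],
            ins_rate >= 0, del_rate >= 0, size_p > 0, size_p <= 1,
            flank >= inter_indel_space, noise_rate >= 0,
            complex_fraction >= 0, complex_fraction <= 1)
  if (!all(tree$tip.label %in% roster$taxon))
    stop("tree leaves absent from roster: ",
         paste(setdiff(tree$tip.label, roster$taxon), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("simulation tree needs branch lengths")
  structure(list(tree = tree, roster = roster, n_proteins = n_proteins,
                 length_range = length_range, ins_rate = ins_rate,
                 del_rate = del_rate, size_p = size_p,
                 flank = as.integer(flank),
                 inter_indel_space = as.integer(inter_indel_space),
                 noise_rate = noise_rate,
                 complex_fraction = complex_fraction,
                 terminal_only = terminal_only,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# expected pattern-level call for a single-event region under full
# sampling: carriers = leaves below the event branch
expected_simple_call <- function(carriers, kind, idx) {
  all_taxa <- idx$tips
  other <- setdiff(all_taxa, carriers)
  res <- if (kind == "insertion") carriers else other
  gap <- setdiff(all_taxa, res)
  if (length(res) == 1L)
    return(list(type = "singleton", polarity = "insertion",
                clade = res))
  if (length(gap) == 1L)
    return(list(type = "singleton", polarity = "deletion",
                clade = gap))
  # carriers are always a rooted clade; the complement is one only for a
  # split adjacent to a binary root
  other_strict <- rooted_monophyletic(other, idx)
  clade <- if (other_strict) {
    if (length(gap) < length(res)) gap else res
  } else carriers
  list(type = "CDI", polarity = NA_character_, clade = sort(clade))
}

#' Simulate an alignment corpus with a ground-truth event log
#'
#' For each protein, a conserved ancestral backbone of the drawn length
#' is laid out; the number of indel events is Poisson with mean
#' `(ins_rate + del_rate) * length * total tree length`, each event is
#' assigned a branch (probability proportional to branch length), a kind
#' (insertion vs deletion in proportion to the rates) and a geometric
#' length.  An insertion on branch *b* yields residues in exactly the
#' leaves below *b* and gaps elsewhere; a deletion yields gaps in
#' exactly the leaves below *b*.  Every event region is flanked by
#' `flank` columns of identical residues, so regions never merge and
#' extraction at any threshold recovers the planted spans exactly.
#' Residues inside event regions are deliberately varied across carriers
#' so the columns score as variable.  If the drawn events do not fit the
#' protein (rates too high), the draw is retried a bounded number of
#' times before erroring.
#'
#' @param config A [simulation_config()].
#' @return Object of class `sim_corpus`: list with `alignments` (named
#'   list of `aa_alignment`), `events` (the event log: one row per
#'   event, with region spans in final alignment coordinates, the branch
#'   and its leaf set, and the expected downstream call), `tree`,
#'   `roster`, `sampled` (taxa per alignment) and `config`.
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- config$tree
  idx <- tree_index(tree)
  ntip <- idx$ntip
  tips <- idx$tips
  edge <- tree$edge
  elen <- tree$edge.length
  elig <- seq_len(nrow(edge))
  if (config$terminal_only) elig <- which(edge[, 2L] <= ntip)
  tot_len <- sum(elen[elig])
  rate <- config$ins_rate + config$del_rate
  p_ins <- if (rate > 0) config$ins_rate / rate else 0
  fl <- config$flank

  # descendant edges (indices) below the child of each edge
  sub_edges <- function(ei) {
    ch <- edge[ei, 2L]
    if (ch <= ntip) return(integer(0))
    which(edge[, 1L] %in% node_subtree(ch, idx))
  }

  alns <- vector("list", config$n_proteins)
  ev_rows <- list()
  for (pi in seq_len(config$n_proteins)) {
    prot <- sprintf("prot%03d", pi)
    Lrange <- config$length_range[1L]:config$length_range[2L]
    L <- if (length(Lrange) == 1L) Lrange else sample(Lrange, 1L)
    for (try in 1:6) {
      if (try == 6L)
        stop("indel rates too high: events do not fit protein ", prot)
      n_ev <- stats::rpois(1L, rate * L * tot_len)
      events <- if (n_ev > 0L) data.frame(
        branch = sample(elig, n_ev, replace = TRUE,
                        prob = elen[elig] / tot_len),
        kind = ifelse(stats::runif(n_ev) < p_ins, "insertion", "deletion"),
        len = stats::rgeom(n_ev, config$size_p) + 1L) else NULL
      # nested secondary deletions -> complex regions
      if (!is.null(events)) {
        events$sec_branch <- NA_integer_
        events$sec_len <- NA_integer_
        events$sec_off <- NA_integer_
        for (k in seq_len(n_ev)) {
          if (events$kind[k] != "insertion" || events$len[k] < 3L) next
          se <- sub_edges(events$branch[k])
          if (length(se) == 0L) next
          if (stats::runif(1L) >= config$complex_fraction) next
          events$sec_branch[k] <- if (length(se) == 1L) se else sample(se, 1L)
          events$sec_len[k] <- sample.int(events$len[k] - 2L, 1L)
          events$sec_off[k] <- sample.int(events$len[k] - 1L -
                                          events$sec_len[k], 1L)
        }
      }
      n_noise <- stats::rpois(1L, config$noise_rate * L)
      used <- fl + n_noise * (1L + fl) +
        if (is.null(events)) 0L else sum(events$len + fl)
      if (used <= L) break
    }
    # assemble blocks: leading flank, then regions and noise slots in
    # random order each followed by a flank, then conserved filler
    n_reg <- if (is.null(events)) 0L else nrow(events)
    items <- c(seq_len(n_reg), rep(0L, n_noise))  # region id, 0 = noise slot
    if (length(items) > 1L) items <- items[sample(length(items))]

    cols <- list()
    conserved_block <- function(w) {
      if (w <= 0L) return(NULL)
      matrix(rep(sample(AA_CODES, w, replace = TRUE), each = ntip),
             nrow = ntip)
    }
    cycled <- function(rows, w, phase = 0L) {
      # distinct residues across carriers so event columns stay variable
      m <- matrix("-", nrow = ntip, ncol = w)
      for (j in seq_len(w))
        m[rows, j] <- AA_CODES[((seq_along(rows) + j + phase) %% 20L) + 1L]
      m
    }
    cols[[length(cols) + 1L]] <- conserved_block(fl)
    pos <- fl  # columns emitted so far (0-based next start)
    for (k in items) {
      if (k > 0L) {
        ev <- events[k, ]
        carriers_idx <- match(idx$desc[[edge[ev$branch, 2L]]], tips)
        w <- ev$len
        rows <- if (ev$kind == "insertion") carriers_idx
                else setdiff(seq_len(ntip), carriers_idx)
        block <- cycled(rows, w, phase = pos)
        n_events_region <- 1L
        if (!is.na(ev$sec_branch)) {
          sub_idx <- match(idx$desc[[edge[ev$sec_branch, 2L]]], tips)
          block[sub_idx, (ev$sec_off + 1L):(ev$sec_off + ev$sec_len)] <- "-"
          n_events_region <- 2L
        }
        cols[[length(cols) + 1L]] <- block
        carriers <- tips[carriers_idx]
        region_kind <- if (n_events_region == 1L) "simple" else "complex"
        exp_call <- if (region_kind == "simple")
          expected_simple_call(carriers, ev$kind, idx)
        else list(type = NA_character_, polarity = NA_character_,
                  clade = character(0))
        ch <- edge[ev$branch, 2L]
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          protein = prot, region = k, event = 1L, kind = ev$kind,
          branch = if (ch <= ntip) tips[ch] else paste0("n", ch),
          branch_taxa = paste(sort(carriers), collapse = ","),
          start = pos, end = pos + w, length = w,
          n_events_region = n_events_region, region_kind = region_kind,
          expected_type = exp_call$type,
          expected_polarity = exp_call$polarity,
          expected_clade = paste(exp_call$clade, collapse = ","),
          stringsAsFactors = FALSE)
        if (n_events_region == 2L) {
          ch2 <- edge[ev$sec_branch, 2L]
          ev_rows[[length(ev_rows) + 1L]] <- data.frame(
            protein = prot, region = k, event = 2L, kind = "deletion",
            branch = if (ch2 <= ntip) tips[ch2] else paste0("n", ch2),
            branch_taxa = paste(sort(tips[match(idx$desc[[ch2]], tips)]),
                                collapse = ","),
            start = pos + ev$sec_off, end = pos + ev$sec_off + ev$sec_len,
            length = ev$sec_len,
            n_events_region = 2L, region_kind = "complex",
            expected_type = NA_character_,
            expected_polarity = NA_character_,
            expected_clade = "",
            stringsAsFactors = FALSE)
        }
        pos <- pos + w
      } else {
        # substitution-noise column: gap-free, partially conserved
        f <- stats::runif(1L, 0.25, 0.95)
        k_dom <- max(1L, min(ntip, round(f * ntip)))
        dom <- sample(AA_CODES, 1L)
        col <- rep(dom, ntip)
        rest <- sample(ntip, ntip - k_dom)
        col[rest] <- setdiff(AA_CODES, dom)[
          ((seq_along(rest)) %% 19L) + 1L]
        cols[[length(cols) + 1L]] <- matrix(col, ncol = 1L)
        pos <- pos + 1L
      }
      cols[[length(cols) + 1L]] <- conserved_block(fl)
      pos <- pos + fl
    }
    if (L - used > 0L) cols[[length(cols) + 1L]] <- conserved_block(L - used)
    m <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
    recs <- apply(m, 1L, paste, collapse = "")
    names(recs) <- tips
    alns[[pi]] <- alignment(recs)
  }
  names(alns) <- sprintf("prot%03d", seq_len(config$n_proteins))
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(protein = character(0), region = integer(0),
               event = integer(0), kind = character(0),
               branch = character(0), branch_taxa = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               n_events_region = integer(0), region_kind = character(0),
               expected_type = character(0),
               expected_polarity = character(0),
               expected_clade = character(0))
  rownames(events) <- NULL
  structure(list(alignments = alns, events = events, tree = tree,
                 roster = config$roster,
                 sampled = stats::setNames(
                   rep(list(tips), length(alns)), names(alns)),
                 config = config),
            class = "sim_corpus")
}

# all nodes (internal + tips) in the subtree rooted at `node`
node_subtree <- function(node, idx) {
  out <- node
  stack <- node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- idx$children[[nd]]
    if (length(k)) { out <- c(out, k); stack <- c(stack, k) }
  }
  out
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat("Simulated corpus: ", length(x$alignments), " alignments over ",
      length(x$tree$tip.label), " taxa; ",
      sum(x$events$event == 1L), " planted events (",
      sum(x$events$kind == "insertion" & x$events$event == 1L), " insertions, ",
      sum(x$events$kind == "deletion" & x$events$event == 1L),
      " deletions)\n", sep = "")
  invisible(x)
}

#' Remove taxa from selected alignments of a simulated corpus
#'
#' Models patchy taxon sampling: the named sequences are deleted from
#' the named alignments, the per-alignment sampled sets are updated and
#' the ground-truth expectations in the event log are re-labelled —
#' regions whose minority state is no longer observed become `lost`,
#' patterns reduced to one bearer become singletons, and single-event
#' patterns whose defined clade now has an unsampled taxon inside or as
#' immediate sister become `ambiguous`.
#'
#' @param corpus A `sim_corpus`.
#' @param drop_spec Named list: alignment ID -> character vector of taxa
#'   to drop.
#' @return The modified `sim_corpus`.
#' @export
make_missing_taxa <- function(corpus, drop_spec) {
  stopifnot(inherits(corpus, "sim_corpus"), is.list(drop_spec))
  idx <- tree_index(corpus$tree)
  for (aid in names(drop_spec)) {
    drop <- drop_spec[[aid]]
    if (!aid %in% names(corpus$alignments))
      stop("no such alignment: ", aid)
    aln <- corpus$alignments[[aid]]
    sampled <- corpus$sampled[[aid]]
    if (!all(drop %in% sampled))
      stop("drop_spec names unsampled taxa for ", aid, ": ",
           paste(setdiff(drop, sampled), collapse = ", "))
    remain <- setdiff(sampled, drop)
    if (length(remain) < 2L)
      stop("dropping ", length(drop), " taxa leaves fewer than 2 sequences in ",
           aid)
    keep_ids <- names(aln$records)[aln$taxon_of %in% remain]
    corpus$alignments[[aid]] <- alignment(aln$records[keep_ids],
                                          taxon_of = aln$taxon_of[keep_ids])
    corpus$sampled[[aid]] <- remain

    rows <- which(corpus$events$protein == aid & corpus$events$event == 1L &
                  corpus$events$region_kind == "simple")
    for (r in rows) {
      carriers <- strsplit(corpus$events$branch_taxa[r], ",", fixed = TRUE)[[1L]]
      kind <- corpus$events$kind[r]
      res <- if (kind == "insertion") carriers else setdiff(idx$tips, carriers)
      gap <- setdiff(idx$tips, res)
      res <- intersect(res, remain)
      gap <- intersect(gap, remain)
      upd <- relabel_expectation(res, gap, remain, corpus$tree,
                                 corpus$roster, idx)
      corpus$events$expected_type[r] <- upd$type
      corpus$events$expected_polarity[r] <- upd$polarity
      corpus$events$expected_clade[r] <- paste(upd$clade, collapse = ",")
    }
  }
  corpus
}

relabel_expectation <- function(res, gap, remain, tree, roster, idx) {
  if (length(res) == 0L || length(gap) == 0L)
    return(list(type = "lost", polarity = NA_character_, clade = character(0)))
  if (length(res) == 1L)
    return(list(type = "singleton", polarity = "insertion", clade = res))
  if (length(gap) == 1L)
    return(list(type = "singleton", polarity = "deletion", clade = gap))
  pruned <- ape::keep.tip(tree, remain)
  pidx <- tree_index(pruned)
  clade <- pick_clade_side(res, gap, pidx)
  unsampled <- setdiff(roster$taxon, remain)
  unsampled <- intersect(unsampled, idx$tips)
  if (length(unsampled)) {
    v <- mrca_node(clade, idx)
    inside <- setdiff(idx$desc[[v]], clade)
    sisters <- character(0)
    if (v != idx$root) {
      p <- idx$parent[v]
      sisters <- setdiff(idx$desc[[p]], idx$desc[[v]])
    }
    if (any(unsampled %in% c(inside, sisters)))
      return(list(type = "ambiguous", polarity = NA_character_,
                  clade = sort(clade)))
  }
  list(type = "CDI", polarity = NA_character_, clade = sort(clade))
}

#' Construct a BLAST hit table with a known correct selection
#'
#' Fixture generator for the three hit-retention tiers: `zero_hit`
#' contains an E-value 0.0 hit, `mid_tier` four sub-1e-65 hits whose
#' log10 distances to the top hit are 0, 5, 30 and 32 (median cutoff
#' 17.5), `floor_tier` a lone sub-1e-30 hit, and `none` only hits above
#' every threshold.  The expected retained set (under `keep = "near"`)
#' is attached as attribute `expected`.
#'
#' @param scenario One of `"zero_hit"`, `"mid_tier"`, `"floor_tier"`,
#'   `"none"`.
#' @param seed Seed used to shuffle row order.
#' @return Data frame `qseqid`, `sseqid`, `evalue` with attribute
#'   `expected` (list: `retained`, `category`).
#' @export
make_blast_fixture <- function(scenario = c("zero_hit", "mid_tier",
                                            "floor_tier", "none"),
                               seed = 1L) {
  scenario <- match.arg(scenario)
  tab <- switch(scenario,
    zero_hit = list(df = data.frame(sseqid = c("A", "B", "C"),
                                    evalue = c(0, 1e-250, 1e-180)),
                    retained = "A", category = "highly"),
    mid_tier = list(df = data.frame(sseqid = c("A", "B", "C", "D"),
                                    evalue = c(1e-100, 1e-95, 1e-70, 1e-68)),
                    retained = c("A", "B"), category = "moderately"),
    floor_tier = list(df = data.frame(sseqid = c("A", "B"),
                                      evalue = c(1e-40, 1e-20)),
                      retained = "A", category = "poorly"),
    none = list(df = data.frame(sseqid = c("A", "B"),
                                evalue = c(1e-25, 1e-8)),
                retained = character(0), category = "none"))
  df <- tab$df
  df$qseqid <- "query1"
  set.seed(seed)
  df <- df[sample(nrow(df)), c("qseqid", "sseqid", "evalue")]
  rownames(df) <- NULL
  attr(df, "expected") <- list(retained = tab$retained,
                               category = tab$category)
  df
}
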