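# End-to-end pipeline: screen -> extract -> phylo -> report.

#' Summarize the phylogenetic partition of simple indels
#'
#' Counts calls per type (singleton / CDI / homoplastic / ambiguous) and
#' renders percentages of the simple-indel total — and, when
#' `n_total_indels` is supplied, of all indels — with one decimal.
#' The four types partition the simple set, so the counts always sum to
#' the number of calls.
#'
#' @param calls An `indel_calls` data frame (or anything with a `type`
#'   column).
#' @param n_total_indels Optional total indel count (simple + complex)
#'   for the percentage-of-all column.
#' @return Data frame with columns `type`, `n`, `pct_simple` and
#'   optionally `pct_all`.
#' @examples
#' calls <- data.frame(type = rep(c("singleton", "ambiguous"), c(550, 195)))
#' summarize_partition(calls)  # 61.0% more than half singletons
#' @export
summarize_partition <- function(calls, n_total_indels = NULL) {
  types <- c("singleton", "CDI", "homoplastic", "ambiguous")
  n <- as.integer(table(factor(calls$type, levels = types)))
  total <- sum(n)
  out <- data.frame(type = types, n = n,
                    pct_simple = if (total > 0) round(100 * n / total, 1)
                                 else rep(0, 4L),
                    stringsAsFactors = FALSE)
  if (!is.null(n_total_indels))
    out$pct_all <- if (n_total_indels > 0)
      round(100 * n / n_total_indels, 1) else rep(0, 4L)
  out
}

#' Run the full indel analysis pipeline
#'
#' Stages, in order: (1) screening — fragment removal per alignment and
#' taxon-coverage categorization, with `flawed` alignments discarded;
#' (2) indel extraction at the chosen similarity threshold (optionally a
#' threshold survey first, with `threshold = "auto"` picking the survey
#' optimum); (3) phylogenetic typing of simple indels, polarization and
#' I:D ratios; (4) summary tables, written as TSVs when `out_dir` is
#' given.  The run is deterministic: two runs on the same inputs and
#' settings produce identical outputs.
#'
#' @param alignments Named list of `aa_alignment` objects, or a
#'   directory containing aligned FASTA files (`.fa`/`.fasta`).
#' @param tree Rooted reference `phylo` tree (or newick path).
#' @param roster A `taxon_roster` (or TSV path).
#' @param out_dir Optional output directory for TSV reports and the run
#'   log; created if needed.
#' @param threshold Similarity threshold percent, or `"auto"` to select
#'   the survey optimum.
#' @param inter_indel_space Merge distance in conserved columns.
#' @param min_frac Fragment filter fraction (see [drop_incomplete()]).
#' @param drop_flawed Discard alignments categorized `flawed`
#'   (default `TRUE`).
#' @param survey Also compute the 25-100% threshold survey (implied by
#'   `threshold = "auto"`).
#' @param quiet Suppress progress messages.
#' @return Object of class `indel_run`: list with `indels` (pooled
#'   `indel_set` rows), `calls`, `partition`, `id_ratios`, `categories`,
#'   `survey` (or `NULL`), `per_protein` counts, `sizes`, `settings`.
#' @export
run_pipeline <- function(alignments, tree, roster, out_dir = NULL,
                         threshold = 50, inter_indel_space = 3L,
                         min_frac = 0.5, drop_flawed = TRUE,
                         survey = FALSE, quiet = FALSE) {
  if (is.character(roster)) roster <- read_taxon_roster(roster)
  if (is.character(tree)) tree <- read_tree(tree)
  if (is.character(alignments)) {
    paths <- list.files(alignments, pattern = "\\.(fa|fasta)$",
                        full.names = TRUE)
    if (length(paths) == 0L) stop("no FASTA files in ", alignments)
    alignments <- stats::setNames(lapply(paths, read_alignment),
                                  sub("\\.(fa|fasta)$", "", basename(paths)))
  }
  stopifnot(length(alignments) > 0L)
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("aln%03d", seq_along(alignments))
  say <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    say(msg)
    log_lines <<- c(log_lines, msg)
  }

  note("settings: threshold=", threshold,
       " inter_indel_space=", inter_indel_space,
       " min_frac=", min_frac, " drop_flawed=", drop_flawed)

  # stage 1: screening
  cats <- data.frame(cluster = names(alignments),
                     category = NA_character_, n_missing = NA_integer_,
                     kept = NA, stringsAsFactors = FALSE)
  screened <- list()
  for (i in seq_along(alignments)) {
    id <- names(alignments)[i]
    aln <- tryCatch(drop_incomplete(alignments[[i]], frac = min_frac),
                    error = function(e)
                      stop("screening failed for ", id, ": ",
                           conditionMessage(e)))
    cat_i <- categorize_alignment(unique(unname(aln$taxon_of)), roster)
    cats$category[i] <- cat_i$label
    cats$n_missing[i] <- length(cat_i$missing)
    keep <- !(drop_flawed && cat_i$label == "flawed")
    cats$kept[i] <- keep
    if (keep) screened[[id]] <- aln
    else note("discarded ", id, " (flawed: ",
              length(cat_i$missing), " taxa missing)")
  }
  note(length(screened), " of ", length(alignments),
       " alignments passed screening")
  if (length(screened) == 0L) {
    note("0 alignments passed screening; no indels to extract")
    res <- structure(list(indels = NULL, calls = NULL,
                          partition = summarize_partition(
                            data.frame(type = character(0))),
                          id_ratios = NULL, categories = cats,
                          survey = NULL, per_protein = NULL, sizes = NULL,
                          settings = list(threshold = threshold,
                                          inter_indel_space = inter_indel_space,
                                          min_frac = min_frac),
                          log = log_lines),
                     class = "indel_run")
    if (!is.null(out_dir)) write_run(res, out_dir)
    return(res)
  }

  # stage 2: extraction (and optional survey)
  surv <- NULL
  if (identical(threshold, "auto") || isTRUE(survey)) {
    surv <- threshold_survey(screened,
                             inter_indel_space = inter_indel_space)
    if (identical(threshold, "auto")) {
      threshold <- select_optimal_threshold(surv)
      note("survey optimum threshold: ", threshold, "%")
    }
  }
  sets <- lapply(names(screened), function(id)
    extract_indels(screened[[id]], threshold = threshold,
                   inter_indel_space = inter_indel_space, cluster = id))
  indels <- do.call(rbind, sets)
  class(indels) <- c("indel_set", "data.frame")
  note(nrow(indels), " indels extracted (",
       sum(indels$kind == "simple"), " simple, ",
       sum(indels$kind == "complex"), " complex)")

  # stage 3: phylogenetic interpretation
  calls <- do.call(rbind, lapply(names(screened), function(id)
    classify_events(sets[[match(id, names(screened))]], screened[[id]],
                    tree, roster)))
  class(calls) <- c("indel_calls", "data.frame")
  partition <- summarize_partition(calls, n_total_indels = nrow(indels))
  ratios <- compute_id_ratios(calls, roster)

  per_protein <- do.call(rbind, lapply(names(screened), function(id) {
    s <- sets[[match(id, names(screened))]]
    data.frame(cluster = id,
               length = mean(ungapped_lengths(screened[[id]])),
               n_simple = sum(s$kind == "simple"),
               n_complex = sum(s$kind == "complex"),
               stringsAsFactors = FALSE)
  }))
  sizes <- size_distribution(indels, by = "kind")

  res <- structure(list(indels = indels, calls = calls,
                        partition = partition, id_ratios = ratios,
                        categories = cats, survey = surv,
                        per_protein = per_protein, sizes = sizes,
                        settings = list(threshold = threshold,
                                        inter_indel_space = inter_indel_space,
                                        min_frac = min_frac),
                        log = log_lines),
                   class = "indel_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(res$indels)) {
    rep_df <- res$indels
    if (!is.null(res$calls) && nrow(res$calls)) {
      key <- paste(rep_df$cluster, rep_df$start, rep_df$end)
      ckey <- paste(res$calls$cluster, res$calls$start, res$calls$end)
      m <- match(key, ckey)
      rep_df$type <- res$calls$type[m]
      rep_df$polarity <- res$calls$polarity[m]
      rep_df$bearing_taxa <- res$calls$bearing_taxa[m]
    }
    write_indel_report(rep_df, file.path(out_dir, "indels.tsv"))
  }
  tsv(res$categories, "categories.tsv")
  tsv(res$partition, "partition.tsv")
  if (!is.null(res$id_ratios)) tsv(res$id_ratios$per_taxon, "id_ratios.tsv")
  if (!is.null(res$survey)) tsv(as.data.frame(res$survey), "survey.tsv")
  if (!is.null(res$per_protein)) tsv(res$per_protein, "per_protein.tsv")
  s <- res$settings
  writeLines(c(paste0("threshold=", s$threshold),
               paste0("inter_indel_space=", s$inter_indel_space),
               paste0("min_frac=", s$min_frac)),
             file.path(out_dir, "config.txt"))
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.indel_run <- function(x, ...) {
  cat("Indel pipeline run\n")
  cat("  alignments kept: ", sum(x$categories$kept), " of ",
      nrow(x$categories), "\n", sep = "")
  if (is.null(x$indels)) {
    cat("  no indels extracted\n")
    return(invisible(x))
  }
  cat("  indels: ", nrow(x$indels), " (",
      sum(x$indels$kind == "simple"), " simple, ",
      sum(x$indels$kind == "complex"), " complex) at threshold ",
      x$settings$threshold, "%\n", sep = "")
  cat("  simple-indel partition:\n")
  print(x$partition, row.names = FALSE)
  cat("  pooled I:D ratio: ", round(x$id_ratios$pooled$ratio, 2),
      " (", x$id_ratios$pooled$insertions, ":",
      x$id_ratios$pooled$deletions, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.indel_run <- function(object, ...) {
  print(object)
  if (!is.null(object$sizes)) print(object$sizes)
  if (!is.null(object$id_ratios)) print(object$id_ratios)
  invisible(object)
}
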