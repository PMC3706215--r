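quartet <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
quartet_roster <- taxon_roster(data.frame(taxon = c("A", "B", "C", "D"),
                                          group = "G"))

# alignment over the quartet taxa with one planted block
quartet_aln <- function(block) {
  withr::local_seed(17)
  planted_alignment(list(block))
}

call_one <- function(block, tree = quartet, roster = quartet_roster) {
  aln <- quartet_aln(block)
  idx <- extract_indels(aln)
  stopifnot(nrow(idx) == 1L)
  classify_events(idx, aln, tree, roster)
}

test_that("presence patterns map to singleton, CDI and homoplastic calls", {
  # one bearer of residues among gaps: singleton insertion
  cl <- call_one(c(A = "W", B = "-", C = "-", D = "-"))
  expect_equal(cl$type, "singleton")
  expect_equal(cl$polarity, "insertion")
  expect_equal(cl$taxon, "A")

  # one bearer of the gap among residues: singleton deletion
  cl <- call_one(c(A = "-", B = "C", C = "Y", D = "V"))
  expect_equal(cl$type, "singleton")
  expect_equal(cl$polarity, "deletion")
  expect_equal(cl$taxon, "A")

  # presence {A,B} on ((A,B),(C,D)): clade-defining
  cl <- call_one(c(A = "WY", B = "CD", C = "--", D = "--"))
  expect_equal(cl$type, "CDI")
  expect_equal(cl$clade[[1]], c("A", "B"))

  # presence {A,C}: two independent events under any rooting
  cl <- call_one(c(A = "WY", B = "--", C = "CD", D = "--"))
  expect_equal(cl$type, "homoplastic")
  expect_equal(fitch_min_changes(quartet, c("A", "C")), 2)

  # a deletion shared by a minority clade defines that clade
  tree6 <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  roster6 <- taxon_roster(data.frame(taxon = LETTERS[1:6], group = "G"))
  withr::local_seed(18)
  blocks <- list(c(A = "--", B = "--", C = "WY", D = "CE", E = "GH",
                   F = "IK"))
  aln <- planted_alignment(blocks)
  cl <- classify_events(extract_indels(aln), aln, tree6, roster6)
  expect_equal(cl$type, "CDI")
  expect_equal(cl$clade[[1]], c("A", "B"))
})

test_that("missing sister or nested taxa make single-event calls ambiguous", {
  tree6 <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  roster6 <- taxon_roster(data.frame(taxon = LETTERS[1:6], group = "G"))
  withr::local_seed(19)
  # pattern {A,B} with the sister clade member C unsampled
  blocks <- list(c(A = "WY", B = "CD", E = "--", F = "--", D = "--"))
  aln <- planted_alignment(blocks)
  idx <- extract_indels(aln)
  cl <- classify_events(idx, aln, tree6, roster6)
  expect_equal(cl$type, "ambiguous")

  # same pattern fully sampled is a CDI
  blocks <- list(c(A = "WY", B = "CD", C = "--", D = "--", E = "--",
                   F = "--"))
  aln <- planted_alignment(blocks)
  cl <- classify_events(extract_indels(aln), aln, tree6, roster6)
  expect_equal(cl$type, "CDI")

  # an unsampled taxon far from the bearing clade does not block the call
  blocks <- list(c(A = "WY", B = "CD", C = "--", D = "--", E = "--"))
  aln <- planted_alignment(blocks)
  cl <- classify_events(extract_indels(aln), aln, tree6, roster6)
  expect_equal(cl$type, "CDI")

  # singleton status takes precedence over ambiguity
  blocks <- list(c(A = "W", B = "-", E = "-", F = "-", D = "-"))
  aln <- planted_alignment(blocks)
  cl <- classify_events(extract_indels(aln), aln, tree6, roster6)
  expect_equal(cl$type, "singleton")
})

test_that("single-event compatibility equals the exhaustive min-change oracle", {
  withr::local_seed(53)
  trees <- list()
  for (n in 4:6) {
    all_t <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = LETTERS[1:n])
    pick <- if (n == 6) sample(length(all_t), 30) else seq_along(all_t)
    for (k in pick) {
      tr <- ape::root(all_t[[k]], outgroup = "A", resolve.root = TRUE)
      tr$edge.length <- rep(1, nrow(tr$edge))
      trees[[length(trees) + 1L]] <- tr
    }
  }
  for (tr in trees) {
    n <- length(tr$tip.label)
    for (code in 1:(2^n - 2)) {
      bearing <- tr$tip.label[as.logical(intToBits(code)[1:n])]
      got <- single_event_compatible(tr, bearing)
      want <- fitch_min_changes(tr, bearing) == 1
      expect_equal(got, want)
    }
  }
})

test_that("soft polytomies never create spurious homoplasy", {
  poly <- ape::read.tree(text = "((A,B,C,D),(E,F));")
  # union of two polytomy children is compatible with some resolution
  expect_true(single_event_compatible(poly, c("A", "B")))
  expect_true(single_event_compatible(poly, c("A", "C", "D")))
  # but splitting the resolved clade (E,F) is not
  expect_false(single_event_compatible(poly, c("A", "E")))
})

test_that("polarization reads the direction off uniform non-bearers", {
  withr::local_seed(29)
  ids <- paste0("s", 1:10)
  blocks <- list(stats::setNames(c("ACD", rep("---", 9)), ids))
  aln <- planted_alignment(blocks)
  idx <- extract_indels(aln)
  rec <- classify_indel(aln, c(idx$start[1], idx$end[1]))
  expect_equal(polarize_singleton(rec), "insertion")

  blocks <- list(stats::setNames(
    c("---", paste0(c("A", "C", "D", "E", "F", "G", "H", "I", "K"), "CD")),
    ids))
  aln <- planted_alignment(blocks)
  idx <- extract_indels(aln)
  rec <- classify_indel(aln, c(idx$start[1], idx$end[1]))
  expect_equal(polarize_singleton(rec), "deletion")

  # two bearers: not a singleton
  blocks <- list(stats::setNames(c("ACD", "AWE", rep("---", 8)), ids))
  aln <- planted_alignment(blocks)
  rec <- classify_indel(aln, c(5, 8))
  expect_error(polarize_singleton(rec), "not a singleton")
})

test_that("I:D tables report per-taxon, pooled and mean-of-taxa ratios", {
  ro <- taxon_roster(data.frame(taxon = c("Entamoeba", "Other"),
                                group = c("Amoebozoa", "Metazoa")))
  calls <- data.frame(
    type = "singleton",
    polarity = rep(c("insertion", "deletion"), c(22, 15)),
    taxon = "Entamoeba", stringsAsFactors = FALSE)
  tab <- compute_id_ratios(calls, ro)
  ent <- tab$per_taxon[tab$per_taxon$taxon == "Entamoeba", ]
  expect_equal(ent$insertions, 22L)
  expect_equal(ent$deletions, 15L)
  expect_equal(round(ent$ratio, 2), 1.47)
  # a taxon with no singletons has NA ratio, zero counts
  oth <- tab$per_taxon[tab$per_taxon$taxon == "Other", ]
  expect_equal(oth$insertions + oth$deletions, 0L)
  expect_true(is.na(oth$ratio))
  expect_equal(tab$pooled$ratio, 22 / 15)
  expect_equal(tab$mean_of_taxa, 22 / 15)

  # equal counts give ratio 1; deletions = 0 gives Inf
  calls2 <- data.frame(type = "singleton",
                       polarity = c("insertion", "deletion",
                                    "insertion", "insertion"),
                       taxon = c("Entamoeba", "Entamoeba", "Other", "Other"))
  tab2 <- compute_id_ratios(calls2, ro)
  expect_equal(tab2$per_taxon$ratio[tab2$per_taxon$taxon == "Entamoeba"], 1)
  expect_equal(tab2$per_taxon$ratio[tab2$per_taxon$taxon == "Other"], Inf)
  expect_equal(tab2$mean_of_taxa, 1)  # only taxa with >= 1 deletion
  # empty input gives a zero table
  tab0 <- compute_id_ratios(calls2[0, ], ro)
  expect_equal(tab0$pooled$insertions, 0L)
  expect_true(is.na(tab0$pooled$ratio))
})

test_that("size distributions bin by integer class with summary fractions", {
  x <- data.frame(width = rep(1L, 10), kind = "simple")
  sd1 <- size_distribution(x)
  expect_equal(sd1$histogram$n, 10L)
  expect_equal(sd1$histogram$size, 1L)
  expect_equal(sd1$summary$median, 1)
  expect_equal(sd1$summary$frac_1aa, 1)

  x <- data.frame(width = c(1, 2, 2, 3), kind = "simple")
  expect_equal(size_distribution(x)$summary$median, 2)

  # geometric law: observed tail fractions near the closed-form CDF
  withr::local_seed(61)
  p <- 0.427
  w <- rgeom(4000, p) + 1L
  x <- data.frame(width = w, kind = "simple")
  s <- size_distribution(x)$summary
  expect_equal(s$frac_le5, 1 - (1 - p)^5, tolerance = 0.03)
  expect_equal(s$frac_le10, 1 - (1 - p)^10, tolerance = 0.03)
  expect_equal(s$frac_1aa, p, tolerance = 0.05)
})

test_that("count-vs-length regression matches closed-form least squares", {
  # exact line: y = 0.01 x - 1
  df <- data.frame(length = c(300, 500, 900),
                   n_simple = 0.01 * c(300, 500, 900) - 1,
                   n_complex = 0.02 * c(300, 500, 900) + 3)
  fit <- suppressWarnings(indel_count_vs_length_regression(df))
  expect_equal(fit$slope[fit$kind == "simple"], 0.01)
  expect_equal(fit$intercept[fit$kind == "simple"], -1)
  expect_equal(fit$r_squared, c(1, 1))

  # proteins under 250aa are excluded before fitting
  df2 <- rbind(df, data.frame(length = 100, n_simple = 50, n_complex = 50))
  fit2 <- suppressWarnings(indel_count_vs_length_regression(df2))
  expect_equal(fit2$n, c(3L, 3L))
  expect_equal(fit2$slope, fit$slope)

  expect_error(indel_count_vs_length_regression(df[1:2, ]), "at least 3")
  dfc <- data.frame(length = rep(400, 4), n_simple = 1:4, n_complex = 1:4)
  expect_error(indel_count_vs_length_regression(dfc), "degenerate|constant")

  withr::local_seed(71)
  dfr <- data.frame(length = runif(40, 250, 1000))
  dfr$n_simple <- rpois(40, 1 + 0.003 * dfr$length)
  dfr$n_complex <- rpois(40, 2 + 0.015 * dfr$length)
  fit <- indel_count_vs_length_regression(dfr)
  oracle <- ols_oracle(dfr$length, dfr$n_simple)
  expect_equal(fit$slope[fit$kind == "simple"], oracle$slope)
  expect_equal(fit$intercept[fit$kind == "simple"], oracle$intercept)
  expect_equal(fit$r_squared[fit$kind == "simple"], oracle$r_squared)
})

test_that("group conservation tallies consensus matches per major group", {
  ro <- taxon_roster(data.frame(taxon = c("m1", "m2", "f1", "f2"),
                                group = c("Metazoa", "Metazoa",
                                          "Fungi", "Fungi")))
  # 6 columns; consensus at 70% needs >= 3/4 sharing a residue
  aln <- alignment(c(m1 = "AAAAAA",
                     m2 = "AAAAAC",
                     f1 = "AACAAA",
                     f2 = "AAC-AA"))
  # col fractions: 4/4, 4/4, 2/4, 3/4, 4/4, 3/4 -> consensus cols 1,2,4,5,6
  gc <- group_conservation(list(aln), ro, consensus_threshold = 70)
  met <- gc[gc$group == "Metazoa", ]
  fun <- gc[gc$group == "Fungi", ]
  expect_equal(met$n_columns, 5L)
  # Metazoa matches consensus A at cols 1,2,4,5 but m2 breaks col 6
  expect_equal(met$n_matches, 4L)
  expect_equal(met$pct_conserved, 80)
  # Fungi: col 4 has a gap in f2 (mismatch); matches at 1,2,5,6
  expect_equal(fun$n_matches, 4L)

  # a group identical to the consensus everywhere scores 100%
  aln2 <- alignment(c(m1 = "AAA", m2 = "AAA", f1 = "AAA", f2 = "CCC"))
  gc2 <- group_conservation(list(aln2), ro)
  expect_equal(gc2$pct_conserved[gc2$group == "Metazoa"], 100)
  expect_equal(gc2$pct_conserved[gc2$group == "Fungi"], 0)

  # group absent everywhere -> NA
  ro3 <- taxon_roster(data.frame(taxon = c("m1", "m2", "f1", "f2", "x"),
                                 group = c("Metazoa", "Metazoa", "Fungi",
                                           "Fungi", "Plants")))
  gc3 <- group_conservation(list(aln2), ro3)
  expect_true(is.na(gc3$pct_conserved[gc3$group == "Plants"]))
})
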