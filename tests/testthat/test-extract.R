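test_that("column conservation uses most-frequent residue over all sequences", {
  # {A,A,A,T}: 3/4 = 75% -> conserved at 50, variable at 80
  aln <- alignment(c(a = "MAM", b = "MAM", c = "MAM", d = "MTM"))
  expect_true(build_conservation_profile(aln, 50)$flags[2])
  expect_false(build_conservation_profile(aln, 80)$flags[2])

  # gaps count in the denominator: {A,A,-,-} is 2/4 = 50%
  aln <- alignment(c(a = "MAM", b = "MAM", c = "M-M", d = "M-M"))
  expect_true(build_conservation_profile(aln, 50)$flags[2])
  expect_false(build_conservation_profile(aln, 55)$flags[2])

  # all-identical alignment is conserved everywhere even at 100%
  aln <- alignment(c(a = "MKLVA", b = "MKLVA", c = "MKLVA"))
  expect_true(all(build_conservation_profile(aln, 100)$flags))

  # 'X' is never the consensus residue
  aln <- alignment(c(a = "MXM", b = "MXM", c = "MXM", d = "MAM"))
  expect_false(build_conservation_profile(aln, 50)$flags[2])
})

test_that("conserved-column count is non-increasing in the threshold", {
  withr::local_seed(301)
  for (i in 1:15) {
    aln <- random_alignment(n_seq = sample(4:12, 1), n_col = 50)
    counts <- vapply(seq(25, 100, 5), function(t)
      sum(build_conservation_profile(aln, t)$flags), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("region delimitation merges runs and excludes unanchored ends", {
  prof <- function(flags, gaps = rep(TRUE, length(flags)))
    structure(list(threshold = 50, flags = flags, any_gap = gaps),
              class = "conservation_profile")
  C <- TRUE; V <- FALSE
  # C C V C C C V C: separator of 3 conserved columns keeps two regions
  got <- identify_indel_regions(prof(c(C, C, V, C, C, C, V, C)), 3)
  expect_spans_equal(got, rbind(c(2, 3), c(6, 7)))
  # C V V C C V V C: 2 conserved separators < 3 -> one merged region
  got <- identify_indel_regions(prof(c(C, V, V, C, C, V, V, C)), 3)
  expect_spans_equal(got, rbind(c(1, 7)))
  # no variable columns -> nothing
  expect_equal(nrow(identify_indel_regions(prof(rep(C, 8)), 3)), 0L)
  # leading/trailing variable columns have no conserved anchor
  got <- identify_indel_regions(prof(c(V, V, C, V, C, V, V)), 3)
  expect_spans_equal(got, rbind(c(3, 4)))
  # spans without any gap are not indels
  got <- identify_indel_regions(prof(c(C, V, C, C, C, V, C),
                                     gaps = c(F, F, F, F, F, T, F)), 3)
  expect_spans_equal(got, rbind(c(5, 6)))
})

test_that("region delimitation agrees with the pairwise-linkage oracle", {
  withr::local_seed(99)
  prof <- function(flags, gaps)
    structure(list(threshold = 50, flags = flags, any_gap = gaps),
              class = "conservation_profile")
  for (i in 1:300) {
    L <- sample(5:40, 1)
    flags <- runif(L) < 0.6
    gaps <- runif(L) < 0.5
    space <- sample(1:4, 1)
    got <- identify_indel_regions(prof(flags, gaps), space)
    want <- region_oracle(flags, gaps, space)
    expect_spans_equal(got, want)
  }
})

test_that("mask states separate simple from complex indels", {
  withr::local_seed(21)
  # 1-column span {A, A, -, A}: two states, simple, length 1
  aln <- planted_alignment(list(c(a = "A", b = "C", c = "-", d = "D")))
  rec <- classify_indel(aln, c(5, 6))
  expect_equal(rec$kind, "simple")
  expect_equal(rec$length, 1L)
  expect_equal(rec$n_states, 2L)

  # full/empty masks over 4 columns: simple of length 4
  aln <- planted_alignment(list(c(a = "ACDE", b = "FGHI", c = "----",
                                  d = "----")))
  rec <- classify_indel(aln, c(5, 9))
  expect_equal(rec$kind, "simple")
  expect_equal(rec$length, 4L)

  # masks {RRRR, RR--, ----}: complex with 3 states
  aln <- planted_alignment(list(c(a = "ACDE", b = "FG--", c = "----",
                                  d = "WYHI")))
  rec <- classify_indel(aln, c(5, 9))
  expect_equal(rec$kind, "complex")
  expect_equal(rec$n_states, 3L)
  expect_true(is.na(rec$length))

  # a span where every sequence carries residues has one state: rejected
  expect_error(classify_indel(aln, c(0, 3)), "not an indel")
})

test_that("terminal gap runs are missing data, not deletion states", {
  withr::local_seed(22)
  blocks <- list(c(a = "AC", b = "DE", c = "--", d = "FG"))
  aln <- planted_alignment(blocks)
  # give sequence d a fragmentary start covering the planted block
  recs <- aln$records
  recs["d"] <- paste0(strrep("-", 7), substr(recs["d"], 8, nchar(recs["d"])))
  aln2 <- alignment(recs)
  rec <- classify_indel(aln2, c(5, 7))
  expect_equal(rec$missing, "d")
  expect_equal(rec$kind, "simple")   # states from a, b, c only
  expect_setequal(rec$states, c("RR", "--"))
})

test_that("extraction is exact on planted alignments and empty on ungapped ones", {
  withr::local_seed(23)
  blocks <- list(
    c(a = "W", b = "-", c = "Y", d = "V"),
    c(a = "AC", b = "DE", c = "--", d = "--"),
    c(a = "---", b = "CDE", c = "FGH", d = "IKL"))
  aln <- planted_alignment(blocks, flank = 5)
  idx <- extract_indels(aln, threshold = 50)
  expect_equal(nrow(idx), 3L)
  expect_spans_equal(cbind(idx$start, idx$end),
                     rbind(c(5, 6), c(11, 13), c(18, 21)))
  expect_equal(idx$kind, rep("simple", 3))

  ungapped <- alignment(c(a = "MKAFWLV", b = "MKCYWLV", c = "MKDEWLV"))
  expect_equal(nrow(extract_indels(ungapped)), 0L)
})

test_that("raising the threshold never splits an indel region", {
  withr::local_seed(77)
  for (i in 1:10) {
    aln <- random_alignment(n_seq = sample(5:10, 1), n_col = 60,
                            gap_p = 0.2)
    grid <- seq(25, 95, 5)
    prev <- NULL
    for (t in grid) {
      spans <- identify_indel_regions(build_conservation_profile(aln, t))
      if (!is.null(prev) && nrow(prev)) {
        for (r in seq_len(nrow(prev))) {
          covering <- which(spans[, "start"] <= prev[r, "start"] &
                            spans[, "end"] >= prev[r, "end"])
          # a previous region is inside at most one current region
          # (it may vanish entirely when its anchors go variable)
          hit <- which(spans[, "start"] < prev[r, "end"] &
                       spans[, "end"] > prev[r, "start"])
          expect_lte(length(hit), 1L)
          if (length(hit) == 1L) expect_equal(hit, covering)
        }
      }
      prev <- spans
    }
  }
})

test_that("1aa indel regions are always simple", {
  withr::local_seed(31)
  co <- simulate_corpus(simulation_config(n_proteins = 6, seed = 8))
  for (id in names(co$alignments)) {
    idx <- extract_indels(co$alignments[[id]])
    expect_true(all(idx$kind[idx$width == 1L] == "simple"))
  }
  # and by construction of the mask rule on random alignments too
  for (i in 1:10) {
    aln <- random_alignment(n_seq = 6, n_col = 40, gap_p = 0.25)
    idx <- extract_indels(aln)
    if (nrow(idx)) expect_true(all(idx$kind[idx$width == 1L] == "simple"))
  }
})

test_that("threshold survey runs the exact grid and totals both kinds", {
  withr::local_seed(41)
  ungapped <- alignment(c(a = "MKAFWLVMMKL", b = "MKCYWLVMMKL",
                          c = "MKDEWLVMMKL"))
  surv <- threshold_survey(list(ungapped))
  expect_equal(surv$threshold, seq(25, 100, 5))
  expect_true(all(surv$n_simple == 0) && all(surv$n_complex == 0))
  expect_error(select_optimal_threshold(surv), "no indels")

  co <- simulate_corpus(simulation_config(n_proteins = 4, seed = 9))
  surv <- threshold_survey(co$alignments)
  expect_equal(nrow(surv), 16L)
  expect_true(all(surv$n_simple + surv$n_complex > 0))
})

test_that("optimum threshold maximizes complex count, ties to the lower", {
  surv <- data.frame(threshold = c(40, 45, 50, 55),
                     n_simple = c(5, 5, 5, 5),
                     n_complex = c(10, 12, 15, 13))
  expect_equal(select_optimal_threshold(surv), 50)
  surv$n_complex <- c(1, 2, 3, 4)          # monotone increasing -> hi end
  expect_equal(select_optimal_threshold(surv), 55)
  surv$n_complex <- c(1, 7, 7, 2)          # tie at 45 and 50 -> 45
  expect_equal(select_optimal_threshold(surv), 45)
})
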