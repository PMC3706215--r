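# Independent oracles and fixture builders used across the suite.

# Exhaustive minimum-change oracle for a binary presence character on a
# rooted binary tree: enumerates every assignment of 0/1 to the internal
# nodes and counts state changes over edges.  Vectorized over the
# 2^Nnode assignments via |a - x| = a(1 - 2x) + x.
fitch_min_changes <- function(tree, bearing) {
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  e <- tree$edge
  A <- as.matrix(expand.grid(rep(list(0:1), m)))  # 2^m x m internal states
  # edge contributions between internal nodes
  int_edges <- e[e[, 2L] > ntip, , drop = FALSE]
  C_int <- rep(0, nrow(A))
  if (nrow(int_edges))
    C_int <- rowSums(abs(A[, int_edges[, 1L] - ntip, drop = FALSE] -
                         A[, int_edges[, 2L] - ntip, drop = FALSE]))
  tip_edges <- e[e[, 2L] <= ntip, , drop = FALSE]
  P <- A[, tip_edges[, 1L] - ntip, drop = FALSE]  # parent state per tip edge
  x <- as.integer(tree$tip.label[tip_edges[, 2L]] %in% bearing)
  min(C_int + as.vector(P %*% (1 - 2 * x)) + sum(x))
}

# Independent region-delimitation oracle: two variable columns belong to
# the same indel region iff every maximal conserved run strictly between
# them is shorter than `space`; region spans run from the first to the
# last member column (0-based half-open).  Columns at or outside the
# outermost conserved columns are excluded, as are spans without gaps.
region_oracle <- function(flags, any_gap, space) {
  empty <- cbind(start = integer(0), end = integer(0))
  cons <- which(flags)
  if (length(cons) == 0L) return(empty)
  lo <- min(cons); hi <- max(cons)
  vars <- which(!flags)
  vars <- vars[vars > lo & vars < hi]
  if (length(vars) == 0L) return(empty)
  linked <- function(i, j) {  # j > i, both variable
    seg <- flags[(i + 1L):(j - 1L)]
    if (j - i == 1L) return(TRUE)
    r <- rle(seg)
    all(r$lengths[r$values] < space)
  }
  grp <- integer(length(vars))
  grp[1L] <- 1L
  for (k in seq_along(vars)[-1L])
    grp[k] <- if (linked(vars[k - 1L], vars[k])) grp[k - 1L] else grp[k - 1L] + 1L
  spans <- t(vapply(split(vars, grp),
                    function(v) c(min(v) - 1L, max(v)), integer(2)))
  keep <- vapply(seq_len(nrow(spans)), function(r)
    any(any_gap[(spans[r, 1L] + 1L):spans[r, 2L]]), logical(1))
  out <- spans[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

# Closed-form OLS via the normal equations, independent of stats::lm.
ols_oracle <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Random gappy alignment for property tests.
random_alignment <- function(n_seq = 8, n_col = 60, gap_p = 0.15,
                             alpha_pool = c("A", "C", "D", "E", "G")) {
  m <- matrix(sample(alpha_pool, n_seq * n_col, replace = TRUE),
              nrow = n_seq)
  m[matrix(runif(n_seq * n_col) < gap_p, nrow = n_seq)] <- "-"
  # keep first and last column residue-only so terminal-gap handling
  # does not silently blank whole sequences
  m[, 1L] <- "M"; m[, n_col] <- "K"
  recs <- apply(m, 1L, paste, collapse = "")
  names(recs) <- paste0("s", seq_len(n_seq))
  alignment(recs)
}

# Tiny planted alignment: identical conserved flanks of width `flank`
# interleaved with explicit segment blocks.  `blocks` is a list of named
# character vectors (one gapped segment per sequence, equal widths; the
# names define the sequence IDs).  The first planted block starts at
# column `flank` (0-based).
planted_alignment <- function(blocks, flank = 5) {
  ids <- names(blocks[[1]])
  stopifnot(length(ids) >= 2)
  mk_flank <- function()
    paste(sample(c("M", "K", "L", "V", "P"), flank, replace = TRUE),
          collapse = "")
  seqs <- stats::setNames(rep(mk_flank(), length(ids)), ids)
  for (b in blocks) {
    stopifnot(setequal(names(b), ids))
    seqs <- paste0(seqs, b[ids], mk_flank())
    names(seqs) <- ids
  }
  alignment(seqs)
}

expect_spans_equal <- function(got, want) {
  got <- matrix(as.integer(got), ncol = 2)
  want <- matrix(as.integer(want), ncol = 2)
  expect_equal(got[order(got[, 1]), , drop = FALSE],
               want[order(want[, 1]), , drop = FALSE],
               ignore_attr = TRUE)
}
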