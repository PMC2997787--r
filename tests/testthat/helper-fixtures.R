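# fixture builders shared across test files; everything is generated in
# code so the repository stays text-only

BASES <- c("A", "C", "G", "T")

random_seq <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, L, replace = TRUE), collapse = "")
}

# derive a second allele differing from `seq` at `n_diff` substitution sites
diverge_allele <- function(seq, n_diff, seed = 1) {
  set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), n_diff)
  v[pos] <- vapply(
    v[pos], function(b) sample(setdiff(BASES, b), 1), character(1)
  )
  paste(v, collapse = "")
}

# alignment of n identical copies of a template with optional injected
# errors: a data.frame(clone, column, state)
alignment_with_errors <- function(template, n, errors = NULL,
                                  spans = NULL) {
  v <- strsplit(template, "")[[1]]
  rows <- replicate(n, v, simplify = FALSE)
  if (!is.null(errors)) {
    for (i in seq_len(nrow(errors))) {
      rows[[errors$clone[i]]][errors$column[i]] <- errors$state[i]
    }
  }
  if (!is.null(spans)) {
    for (i in seq_len(nrow(spans))) {
      r <- rows[[i]]
      if (spans$first[i] > 1) r[seq_len(spans$first[i] - 1)] <- "-"
      if (spans$last[i] < length(r)) r[(spans$last[i] + 1):length(r)] <- "-"
      rows[[i]] <- r
    }
  }
  aligned_clone_set(
    vapply(rows, paste, character(1), collapse = ""),
    ids = sprintf("cl%03d", seq_len(n))
  )
}

# the calibration-style fixture: 82 clones, 58592 scored bases, 95
# injected errors at mutually distinct columns (92 substitutions + 3
# single-base deletions), one partial read making up the odd total
calibration_fixture <- function(seed = 99) {
  set.seed(seed)
  L <- 715
  template <- random_seq(L)
  n <- 82
  # 81 full reads (81*715 = 57915) + one read of 677 -> 58592 scored
  spans <- data.frame(
    first = c(rep(1L, 81), 20L),
    last = c(rep(L, 81), 696L)
  )
  cols <- sample(2:(L - 1), 95)
  clones <- sample(rep_len(seq_len(n), 95))
  v <- strsplit(template, "")[[1]]
  state <- character(95)
  state[1:92] <- vapply(
    cols[1:92], function(cc) sample(setdiff(BASES, v[cc]), 1), character(1)
  )
  state[93:95] <- "-"
  # keep every error inside its clone's read span
  for (i in which(clones == 82)) {
    if (cols[i] < 21 || cols[i] > 695) {
      cols[i] <- sample(setdiff(21:695, cols), 1)
    }
  }
  errors <- data.frame(clone = clones, column = cols, state = state)
  list(
    clones = alignment_with_errors(template, n, errors, spans),
    template = template, errors = errors
  )
}

# four clones in two tight blocks: within-block distance exactly 2,
# every between-block pair exactly 120 (within-block mutations are
# placed at divergent columns, at a third state, so they do not add to
# cross distances) -> UPGMA merges at heights 1, 1, 60
block_fixture <- function() {
  set.seed(7)
  L <- 400
  a <- strsplit(random_seq(L), "")[[1]]
  diff_pos <- sample(L, 120)
  b <- a
  b[diff_pos] <- vapply(
    b[diff_pos], function(bb) sample(setdiff(BASES, bb), 1), character(1)
  )
  third <- function(x, y) setdiff(BASES, c(x, y))[1]
  a2 <- a
  for (p in diff_pos[1:2]) a2[p] <- third(a[p], b[p])
  b2 <- b
  for (p in diff_pos[3:4]) b2[p] <- third(a[p], b[p])
  aligned_clone_set(vapply(
    list(a1 = a, a2 = a2, b1 = b, b2 = b2), paste, character(1),
    collapse = ""
  ))
}

paper_rate <- 95 / 58592
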