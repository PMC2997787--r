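#' Majority-rule consensus of an aligned clone set
#'
#' Each column's consensus state is the most common state among
#' `A, C, G, T, -`. `N` never votes, and positions outside a clone's read
#' span (partial-read padding) do not vote either. Ties are broken by the
#' fixed state order `A < C < G < T < '-'` and recorded in `tie_flag`;
#' tied columns are excluded from deviation calling, so ties can never
#' manufacture errors. Columns with no votes at all (only N or padding)
#' get majority state `-` with `tie_flag = TRUE`.
#'
#' @param clones an [aligned_clone_set()] with at least 2 clones.
#' @return An object of class `consensus_profile`: list with `width`,
#'   `counts` (5 x width integer matrix, rows `A,C,G,T,-`), `majority`
#'   (character vector length `width`), `tie_flag` (logical vector), and
#'   `sequence` (the consensus as a single string).
#' @examples
#' acs <- aligned_clone_set(c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' build_consensus(acs)$sequence
#' @export
build_consensus <- function(clones) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  if (clones$n < 2L) {
    stop("consensus building requires at least 2 clones")
  }
  scored <- scored_matrix(clones)
  counts <- vapply(VOTING_STATES, function(s) {
    colSums((clones$mat == s) & scored)
  }, numeric(clones$width))
  counts <- t(counts) # states x columns
  storage.mode(counts) <- "integer"
  top <- apply(counts, 2, max)
  # which.max returns the first maximum: A < C < G < T < '-' order
  maj_idx <- apply(counts, 2, which.max)
  majority <- VOTING_STATES[maj_idx]
  n_at_max <- colSums(counts == rep(top, each = 5L))
  tie_flag <- n_at_max >= 2L | top == 0L
  majority[top == 0L] <- "-"
  structure(
    list(
      width = clones$width,
      counts = counts,
      majority = majority,
      tie_flag = tie_flag,
      sequence = paste(majority, collapse = "")
    ),
    class = "consensus_profile"
  )
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf(
    "consensus_profile: %d columns, %d tie column(s)\n",
    x$width, sum(x$tie_flag)
  ))
  invisible(x)
}

# transition iff both purines (A,G) or both pyrimidines (C,T)
is_transition <- function(from, to) {
  pur <- c("A", "G")
  (from %in% pur) == (to %in% pur)
}

# strand-symmetric base-pair class of a substitution, consensus -> observed
PAIR_CLASS <- c(
  "A>G" = "AT>GC", "T>C" = "AT>GC",
  "G>A" = "GC>AT", "C>T" = "GC>AT",
  "A>T" = "AT>TA", "T>A" = "AT>TA",
  "A>C" = "AT>CG", "T>G" = "AT>CG",
  "G>T" = "GC>TA", "C>A" = "GC>TA",
  "G>C" = "GC>CG", "C>G" = "GC>CG"
)

#' Call deviations of every clone from the consensus
#'
#' A deviation is a (clone, column) pair where the clone's state differs
#' from the consensus majority state — the operational definition of a
#' candidate PCR error. Positions outside a clone's read span, `N`
#' positions, and tie-flagged consensus columns produce no deviation.
#'
#' @param clones an [aligned_clone_set()].
#' @param consensus a `consensus_profile` (defaults to
#'   `build_consensus(clones)`); must have the same width.
#' @return A data frame with one row per deviation: `clone_id`, `column`
#'   (1-based alignment column), `kind` (`substitution`, `deletion`,
#'   `insertion`), `consensus_state`, `observed_state`, `ti_tv`
#'   (`transition`, `transversion`, `not_applicable`) and `pair_class`
#'   (strand-symmetric substitution class, e.g. `AT>GC`, or
#'   `not_applicable`).
#' @export
call_deviations <- function(clones, consensus = build_consensus(clones)) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  stopifnot(inherits(consensus, "consensus_profile"))
  if (consensus$width != clones$width) {
    stop(sprintf(
      "dimension mismatch: consensus width %d vs alignment width %d",
      consensus$width, clones$width
    ))
  }
  scored <- scored_matrix(clones)
  cons <- matrix(consensus$majority,
    nrow = clones$n, ncol = clones$width, byrow = TRUE
  )
  elig <- scored &
    !matrix(consensus$tie_flag, clones$n, clones$width, byrow = TRUE)
  hit <- elig & clones$mat != cons
  idx <- which(hit, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  obs <- clones$mat[idx]
  ref <- consensus$majority[idx[, 2]]
  kind <- ifelse(
    obs == "-", "deletion",
    ifelse(ref == "-", "insertion", "substitution")
  )
  subst <- kind == "substitution"
  ti_tv <- rep("not_applicable", length(kind))
  ti_tv[subst] <- ifelse(
    is_transition(ref[subst], obs[subst]), "transition", "transversion"
  )
  pair_class <- rep("not_applicable", length(kind))
  pair_class[subst] <- unname(PAIR_CLASS[paste0(ref[subst], ">", obs[subst])])
  data.frame(
    clone_id = clones$ids[idx[, 1]],
    column = unname(idx[, 2]),
    kind = kind,
    consensus_state = ref,
    observed_state = obs,
    ti_tv = ti_tv,
    pair_class = pair_class,
    stringsAsFactors = FALSE
  )
}

#' Count comparable (scored) bases
#'
#' The denominator of the per-site error rate `f`: the total number of
#' positions actually scored, i.e. the sum over clones of non-`N` columns
#' between each clone's first and last non-gap column. Interior deletion
#' columns count toward the denominator (an error event needs a
#' denominator site); terminal gap padding and `N` do not.
#'
#' @param clones an [aligned_clone_set()].
#' @return a single integer count.
#' @export
comparable_bases <- function(clones) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  sum(scored_matrix(clones))
}

#' Summarise an error spectrum
#'
#' Category counts and proportions from a deviation table: by kind
#' (substitution / deletion / insertion over all deviations), by
#' transition/transversion and by strand-symmetric pair class (over
#' substitutions only).
#'
#' @param deviations a data frame from [call_deviations()].
#' @return An object of class `error_spectrum`: list of data frames
#'   `kind`, `ti_tv`, `pair_class` (each with `count` and `proportion`)
#'   plus `n_total` and `n_substitutions`. Proportions are `NA` when the
#'   relevant denominator is zero.
#' @export
summarize_spectrum <- function(deviations) {
  tab <- function(values, levels, denom) {
    counts <- vapply(
      levels, function(l) sum(values == l), integer(1)
    )
    data.frame(
      category = levels,
      count = unname(counts),
      proportion = if (denom > 0) unname(counts) / denom else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  n_total <- nrow(deviations)
  subst <- deviations[deviations$kind == "substitution", , drop = FALSE]
  n_sub <- nrow(subst)
  structure(
    list(
      kind = tab(
        deviations$kind,
        c("substitution", "deletion", "insertion"), n_total
      ),
      ti_tv = tab(subst$ti_tv, c("transition", "transversion"), n_sub),
      pair_class = tab(
        subst$pair_class,
        c("AT>GC", "GC>AT", "AT>TA", "AT>CG", "GC>TA", "GC>CG"), n_sub
      ),
      n_total = n_total,
      n_substitutions = n_sub
    ),
    class = "error_spectrum"
  )
}

#' @export
print.error_spectrum <- function(x, ...) {
  cat(sprintf(
    "error_spectrum: %d deviations (%d substitutions)\n",
    x$n_total, x$n_substitutions
  ))
  for (nm in c("kind", "ti_tv", "pair_class")) {
    df <- x[[nm]]
    df <- df[df$count > 0, , drop = FALSE]
    if (nrow(df) > 0) {
      cat(sprintf("  %s:\n", nm))
      for (i in seq_len(nrow(df))) {
        cat(sprintf(
          "    %-12s %5d  (%.1f%%)\n",
          df$category[i], df$count[i], 100 * df$proportion[i]
        ))
      }
    }
  }
  invisible(x)
}

#' Per-clone deviation counts
#'
#' Histogram input for the binomial goodness-of-fit test: the number of
#' deviations of each clone from the consensus (clones with zero
#' deviations included).
#'
#' @param clones an [aligned_clone_set()].
#' @param deviations optional precomputed deviation table.
#' @return named integer vector, one entry per clone, in clone order.
#' @export
deviations_per_clone <- function(clones, deviations = call_deviations(clones)) {
  counts <- table(factor(deviations$clone_id, levels = clones$ids))
  setNames(as.integer(counts), clones$ids)
}
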