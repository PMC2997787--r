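#' Pairwise difference counts between clones
#'
#' Entry (i, j) counts the mutation events separating clones i and j
#' over the columns scored in both reads (inside both read spans,
#' neither state `N`): substitutions count one per column, and a
#' contiguous interior gap run counts as one event regardless of length
#' (an indel of length 3 is one mutation). Raw difference counts are
#' used rather than p-distances because group separation is naturally
#' expressed in whole base-pair differences; per-pair scored-column
#' counts are returned so users can normalise if they wish.
#'
#' @param clones an [aligned_clone_set()] with at least 2 clones.
#' @return object of class `distance_matrix`: list with `ids`, `d`
#'   (symmetric numeric matrix of event counts), `n_scored` (matrix of
#'   mutually scored column counts).
#' @export
pairwise_distances <- function(clones) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  if (clones$n < 2L) stop("at least 2 clones are required")
  scored <- scored_matrix(clones)
  n <- clones$n
  d <- matrix(0, n, n, dimnames = list(clones$ids, clones$ids))
  ns <- matrix(0L, n, n, dimnames = list(clones$ids, clones$ids))
  for (i in seq_len(n - 1L)) {
    si <- clones$mat[i, ]
    sci <- scored[i, ]
    for (j in (i + 1L):n) {
      both <- sci & scored[j, ]
      ns[i, j] <- ns[j, i] <- sum(both)
      diff_cols <- which(both & si != clones$mat[j, ])
      if (length(diff_cols) == 0L) next
      gi <- si[diff_cols] == "-"
      gj <- clones$mat[j, diff_cols] == "-"
      events <- sum(!gi & !gj) # substitution columns
      for (g in list(gi, gj)) { # one event per contiguous gap run
        cc <- diff_cols[g]
        if (length(cc) > 0L) events <- events + 1L + sum(diff(cc) != 1L)
      }
      d[i, j] <- d[j, i] <- events
    }
  }
  structure(list(ids = clones$ids, d = d, n_scored = ns),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d clones\n", length(x$ids)))
  invisible(x)
}

#' UPGMA clustering of clones
#'
#' Unweighted pair-group average linkage on a pairwise difference-count
#' matrix. Merge heights are half the average linkage distance at each
#' merge (ultrametric node heights: two clones at distance 5 join at
#' height 2.5). Ties are broken deterministically by the
#' lexicographically smallest member id of the candidate pair.
#'
#' @param dm a [pairwise_distances()] result, or a plain symmetric
#'   numeric matrix with dimnames.
#' @return an `hclust`-compatible object of class
#'   `c("upgma_tree", "hclust")` with `merge`, `height` (half the merge
#'   distance), `order`, and `labels`.
#' @export
upgma <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    d <- dm$d
    labels <- dm$ids
  } else {
    d <- as.matrix(dm)
    labels <- rownames(d)
    if (is.null(labels)) labels <- paste0("item", seq_len(nrow(d)))
  }
  n <- nrow(d)
  if (n < 2L) stop("at least 2 items are required")
  # active cluster bookkeeping: hclust codes (negative leaf, positive merge)
  code <- -seq_len(n)
  size <- rep(1L, n)
  rep_id <- labels # lexicographically smallest member id per cluster
  active <- rep(TRUE, n)
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  search <- cur
  search[lower.tri(search, diag = TRUE)] <- Inf
  for (step in seq_len(n - 1L)) {
    best_d <- min(search)
    cand <- which(search == best_d, arr.ind = TRUE)
    if (nrow(cand) > 1L) { # tie: lexicographically smallest member pair
      keys <- vapply(seq_len(nrow(cand)), function(r) {
        paste(sort(rep_id[cand[r, ]]), collapse = "\r")
      }, character(1))
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
    i <- min(cand[1, ])
    j <- max(cand[1, ])
    # hclust merge convention: singletons before clusters, ascending
    pair <- sort(c(code[i], code[j]))
    merge[step, ] <- pair
    height[step] <- best_d / 2
    # average-linkage update into slot i; retire slot j
    others <- setdiff(which(active), c(i, j))
    if (length(others) > 0L) {
      newd <- (size[i] * cur[i, others] + size[j] * cur[j, others]) /
        (size[i] + size[j])
      cur[i, others] <- newd
      cur[others, i] <- newd
      lo <- pmin(i, others)
      hi <- pmax(i, others)
      search[cbind(lo, hi)] <- newd
    }
    size[i] <- size[i] + size[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    code[i] <- step
    active[j] <- FALSE
    search[j, ] <- Inf
    search[, j] <- Inf
  }
  order <- integer(0)
  walk <- function(node) {
    if (node < 0L) {
      order <<- c(order, -node)
    } else {
      walk(merge[node, 1])
      walk(merge[node, 2])
    }
  }
  walk(n - 1L)
  structure(
    list(
      merge = merge, height = height, order = order, labels = labels,
      method = "average", dist.method = "difference count",
      call = match.call()
    ),
    class = c("upgma_tree", "hclust")
  )
}

#' Export a UPGMA dendrogram as Newick
#'
#' Branch lengths reflect the ultrametric merge heights (leaf-to-node
#' depth equals the merge height, i.e. half the linkage distance).
#'
#' @param tree an [upgma()] result.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  # ape::as.phylo.hclust halves hclust heights; pre-double ours so that
  # node depths in the phylo equal our merge heights
  doubled <- tree
  doubled$height <- 2 * tree$height
  class(doubled) <- "hclust"
  phy <- ape::as.phylo(doubled)
  nwk <- ape::write.tree(phy)
  if (is.null(path)) {
    return(nwk)
  }
  writeLines(nwk, path)
  invisible(nwk)
}

# consensus of a subset of clones; single member = the clone itself
subset_clones <- function(clones, ids) {
  keep <- match(ids, clones$ids)
  aligned_clone_set(
    apply(clones$mat[keep, , drop = FALSE], 1, paste, collapse = ""),
    ids = clones$ids[keep]
  )
}

single_clone_profile <- function(clones, id) {
  s <- clones$mat[match(id, clones$ids), ]
  counts <- vapply(
    VOTING_STATES, function(st) as.integer(s == st), integer(clones$width)
  )
  structure(
    list(
      width = clones$width, counts = t(counts), majority = s,
      tie_flag = rep(FALSE, clones$width),
      sequence = paste(s, collapse = "")
    ),
    class = "consensus_profile"
  )
}

#' Cut a dendrogram into putative-allele groups
#'
#' Clones are partitioned at `cut_height` (clusters whose internal
#' merges all sit at or below the cut). Clusters smaller than
#' `min_group_size` are set aside as ungrouped: one or two clones cannot
#' support consensus-based error discrimination. For each retained group
#' a majority-rule consensus is built, and within-group / between-group
#' mean distances are reported so the expected separation (large
#' between-group, small within-group) can be verified.
#'
#' @param clones the [aligned_clone_set()] the tree was built from.
#' @param tree an [upgma()] dendrogram (default: computed from
#'   `clones`).
#' @param cut_height cut level in raw difference units (the scale of
#'   the distance matrix): clusters stay together while their average
#'   linkage distance is at most `cut_height`. The default 50 sits
#'   midway between the within-group (< 10 differences) and
#'   between-group (> 100 differences) separation typical of distinct
#'   alleles of rapidly evolving gene families. (Dendrogram merge
#'   heights are ultrametric, i.e. half the linkage distance, so the
#'   tree is cut at `cut_height / 2`.)
#' @param min_group_size minimum clones per group (default 3).
#' @param dm optional precomputed [pairwise_distances()] (for the
#'   distance summaries).
#' @param refine if `TRUE` (default), run one consensus-reassignment
#'   pass after cutting: every grouped clone is moved to the group
#'   consensus it mismatches least per scored column, and consensuses
#'   are rebuilt. Raw difference counts between two short partial reads
#'   with little mutual overlap can be spuriously small (the triangle
#'   inequality does not hold on partial overlaps), which occasionally
#'   pulls a truncated read into the wrong cluster; comparing against
#'   group consensuses, which cover the whole alignment, repairs this.
#' @return object of class `grouping_result`: list with `groups` (named
#'   list of clone-id vectors), `ungrouped` (clone ids), `consensus`
#'   (named list of `consensus_profile`), `membership` (data frame
#'   clone_id / group_id), `within` and `between` mean distances,
#'   `cut_height`, `min_group_size`, `tree`.
#' @export
cut_groups <- function(clones, tree = NULL, cut_height = 50,
                       min_group_size = 3, dm = NULL, refine = TRUE) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  if (cut_height < 0) stop("cut_height must be >= 0")
  if (is.null(dm) && is.null(tree)) dm <- pairwise_distances(clones)
  if (is.null(tree)) tree <- upgma(dm)
  cl <- stats::cutree(tree, h = cut_height / 2)
  cl <- cl[clones$ids]
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_group_size]
  # group order: decreasing size, then smallest member id
  ord <- order(
    -as.integer(sizes[big]),
    vapply(big, function(g) min(names(cl)[cl == g]), character(1))
  )
  big <- big[ord]
  groups <- setNames(
    lapply(big, function(g) names(cl)[cl == g]),
    if (length(big) > 0) paste0("group", seq_along(big)) else character(0)
  )
  ungrouped <- setdiff(clones$ids, unlist(groups, use.names = FALSE))
  group_consensus <- function(groups) {
    lapply(groups, function(members) {
      if (length(members) >= 2L) {
        build_consensus(subset_clones(clones, members))
      } else {
        single_clone_profile(clones, members)
      }
    })
  }
  consensus <- group_consensus(groups)
  if (refine && length(groups) >= 2L) {
    scored <- scored_matrix(clones)
    mism_rate <- function(id, cp) {
      ri <- match(id, clones$ids)
      use <- scored[ri, ] & !cp$tie_flag
      if (!any(use)) {
        return(Inf)
      }
      sum(clones$mat[ri, use] != cp$majority[use]) / sum(use)
    }
    moved <- FALSE
    for (g in names(groups)) {
      for (id in groups[[g]]) {
        rates <- vapply(consensus, function(cp) mism_rate(id, cp), numeric(1))
        best <- names(groups)[which.min(rates)]
        if (best != g && rates[[best]] < rates[[g]]) {
          groups[[g]] <- setdiff(groups[[g]], id)
          groups[[best]] <- c(groups[[best]], id)
          moved <- TRUE
        }
      }
    }
    if (moved) {
      # groups shrunk below the size floor dissolve into ungrouped
      small <- names(groups)[lengths(groups) < min_group_size]
      ungrouped <- c(ungrouped, unlist(groups[small], use.names = FALSE))
      groups[small] <- NULL
      consensus <- group_consensus(groups)
    }
  }
  within <- NA_real_
  between <- NA_real_
  if (!is.null(dm)) {
    wvals <- unlist(lapply(groups, function(members) {
      if (length(members) < 2L) {
        return(numeric(0))
      }
      sub <- dm$d[members, members]
      sub[upper.tri(sub)]
    }), use.names = FALSE)
    if (length(wvals) > 0) within <- mean(wvals)
    if (length(groups) >= 2L) {
      bvals <- numeric(0)
      gn <- names(groups)
      for (a in seq_along(gn)[-length(gn)]) {
        for (b in (a + 1L):length(gn)) {
          bvals <- c(bvals, as.vector(dm$d[groups[[a]], groups[[b]]]))
        }
      }
      between <- mean(bvals)
    }
  }
  membership <- data.frame(
    clone_id = clones$ids,
    group_id = vapply(clones$ids, function(id) {
      hit <- vapply(groups, function(m) id %in% m, logical(1))
      if (any(hit)) names(groups)[which(hit)[1]] else "ungrouped"
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      groups = groups, ungrouped = ungrouped, consensus = consensus,
      membership = membership, within = within, between = between,
      cut_height = cut_height, min_group_size = min_group_size,
      tree = tree
    ),
    class = "grouping_result"
  )
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf(
    "grouping_result: %d group(s), %d ungrouped clone(s) (cut %g)\n",
    length(x$groups), length(x$ungrouped), x$cut_height
  ))
  for (g in names(x$groups)) {
    cat(sprintf("  %s: %d clones\n", g, length(x$groups[[g]])))
  }
  if (!is.na(x$within)) {
    cat(sprintf(
      "  mean distance within %.2f / between %.2f\n", x$within, x$between
    ))
  }
  invisible(x)
}

#' Flag putative chimeric clones
#'
#' Template switching during multi-template PCR produces recombinant
#' molecules whose segments match different true alleles. The scan is
#' deliberately simple and transparent: tile each clone's read span with
#' windows, assign each window to the group consensus with the fewest
#' mismatches at diagnostic sites (columns where group consensuses
#' differ), merge adjacent windows with the same assignment into
#' segments, and call a chimera when at least two segments assigned to
#' different groups each carry at least `min_diagnostic_sites` of
#' matching diagnostic-site support.
#'
#' @param clones an [aligned_clone_set()] containing the clones to test.
#' @param grouping a [cut_groups()] result with >= 2 groups (fewer
#'   groups yields not-applicable calls: `is_chimera = FALSE`, no
#'   segments).
#' @param window window length in alignment columns (default 100).
#' @param min_diagnostic_sites minimum matching diagnostic sites per
#'   segment (default 5).
#' @param clone_ids which clones to test (default all in `clones`).
#' @return object of class `chimera_calls`: data frame with `clone_id`,
#'   `is_chimera`, `n_segments`, `breakpoints` (comma-separated columns,
#'   empty if none); the per-clone segment tables are in
#'   `attr(, "segments")` (columns `start`, `end`, `group`, `support`).
#' @export
flag_chimeras <- function(clones, grouping, window = 100,
                          min_diagnostic_sites = 5,
                          clone_ids = clones$ids) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  stopifnot(inherits(grouping, "grouping_result"))
  if (window < 1) stop("window must be >= 1")
  gnames <- names(grouping$groups)
  applicable <- length(gnames) >= 2L
  cons_mat <- if (applicable) {
    do.call(rbind, lapply(grouping$consensus, function(cp) cp$majority))
  } else {
    NULL
  }
  diag_cols <- if (applicable) {
    which(apply(cons_mat, 2, function(col) length(unique(col)) > 1L))
  } else {
    integer(0)
  }
  sp <- read_spans(clones)
  segments <- list()
  if (length(clone_ids) == 0L) {
    out <- data.frame(
      clone_id = character(0), is_chimera = logical(0),
      n_segments = integer(0), breakpoints = character(0),
      stringsAsFactors = FALSE
    )
    attr(out, "segments") <- segments
    class(out) <- c("chimera_calls", "data.frame")
    return(out)
  }
  rows <- lapply(clone_ids, function(id) {
    ri <- match(id, clones$ids)
    if (!applicable || is.na(sp[ri, 1])) {
      segments[[id]] <<- data.frame(
        start = integer(0), end = integer(0),
        group = character(0), support = integer(0)
      )
      return(data.frame(
        clone_id = id, is_chimera = FALSE, n_segments = 0L,
        breakpoints = "", stringsAsFactors = FALSE
      ))
    }
    s <- clones$mat[ri, ]
    first <- sp[ri, 1]
    last <- sp[ri, 2]
    starts <- seq(first, last, by = window)
    assign <- character(length(starts))
    for (w in seq_along(starts)) {
      cols <- intersect(diag_cols, starts[w]:min(starts[w] + window - 1L, last))
      cols <- cols[s[cols] != "N"]
      if (length(cols) == 0L) {
        assign[w] <- NA_character_
        next
      }
      mism <- vapply(gnames, function(g) {
        sum(s[cols] != cons_mat[g, cols])
      }, numeric(1))
      best <- which(mism == min(mism))
      assign[w] <- if (length(best) == 1L) gnames[best] else NA_character_
    }
    # windows without a clear assignment inherit their left neighbour
    # (or right, at the start) so segments tile the read span
    if (all(is.na(assign))) {
      segments[[id]] <<- data.frame(
        start = first, end = last, group = NA_character_, support = 0L,
        stringsAsFactors = FALSE
      )
      return(data.frame(
        clone_id = id, is_chimera = FALSE, n_segments = 1L,
        breakpoints = "", stringsAsFactors = FALSE
      ))
    }
    for (w in seq_along(assign)) {
      if (is.na(assign[w]) && w > 1L) assign[w] <- assign[w - 1L]
    }
    for (w in rev(seq_along(assign))) {
      if (is.na(assign[w])) assign[w] <- assign[w + 1L]
    }
    runs <- rle(assign)
    seg_end_w <- cumsum(runs$lengths)
    seg_start_w <- seg_end_w - runs$lengths + 1L
    seg <- data.frame(
      start = starts[seg_start_w],
      end = c(starts[seg_start_w[-1]] - 1L, last),
      group = runs$values,
      stringsAsFactors = FALSE
    )
    seg$support <- vapply(seq_len(nrow(seg)), function(k) {
      cols <- intersect(diag_cols, seg$start[k]:seg$end[k])
      cols <- cols[s[cols] != "N"]
      g <- seg$group[k]
      if (length(cols) == 0L) {
        return(0L)
      }
      other <- setdiff(gnames, g)
      sum(vapply(cols, function(cc) {
        s[cc] == cons_mat[g, cc] &&
          any(cons_mat[other, cc] != cons_mat[g, cc])
      }, logical(1)))
    }, integer(1))
    segments[[id]] <<- seg
    supported <- seg[seg$support >= min_diagnostic_sites, , drop = FALSE]
    is_chim <- length(unique(supported$group)) >= 2L
    bp <- if (is_chim && nrow(supported) >= 2L) {
      chg <- which(supported$group[-1] != supported$group[-nrow(supported)])
      paste(supported$start[chg + 1L], collapse = ",")
    } else {
      ""
    }
    data.frame(
      clone_id = id, is_chimera = is_chim, n_segments = nrow(seg),
      breakpoints = bp, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "segments") <- segments
  class(out) <- c("chimera_calls", "data.frame")
  out
}

#' Sliding-window substitution-rate profile
#'
#' Average number of substitution deviations per scored site per
#' sequence in sliding windows along the alignment. Random polymerase
#' misincorporation should show no positional bias, whereas genuine
#' variability concentrates in rapidly evolving regions (e.g. toxin
#' exons), so a flat profile supports the error interpretation. Default
#' window 100, step 25, mirroring common nucleotide-diversity
#' sliding-window practice.
#'
#' @param clones an [aligned_clone_set()] (typically one group).
#' @param consensus a `consensus_profile` to call deviations against
#'   (default: built from `clones`).
#' @param window window length in columns (<= alignment width).
#' @param step step in columns (>= 1).
#' @return object of class `sliding_window_profile`: data frame with
#'   `start`, `end`, `midpoint`, `substitutions`, `sites`, `rate`
#'   (substitutions per site per sequence; `NA` where no sites scored).
#' @export
sliding_window_profile <- function(clones, consensus = build_consensus(clones),
                                   window = 100, step = 25) {
  stopifnot(inherits(clones, "aligned_clone_set"))
  if (window < 1 || window > clones$width) {
    stop("window must be in 1..alignment width")
  }
  if (step < 1) stop("step must be >= 1")
  dev <- call_deviations(clones, consensus)
  sub_cols <- dev$column[dev$kind == "substitution"]
  site_cov <- colSums(scored_matrix(clones))
  sub_per_col <- tabulate(sub_cols, nbins = clones$width)
  starts <- seq(1L, clones$width - window + 1L, by = step)
  ends <- starts + window - 1L
  subs <- vapply(
    seq_along(starts),
    function(i) sum(sub_per_col[starts[i]:ends[i]]), numeric(1)
  )
  sites <- vapply(
    seq_along(starts),
    function(i) sum(site_cov[starts[i]:ends[i]]), numeric(1)
  )
  out <- data.frame(
    start = starts, end = ends, midpoint = (starts + ends) / 2,
    substitutions = subs, sites = sites,
    rate = ifelse(sites > 0, subs / sites, NA_real_)
  )
  class(out) <- c("sliding_window_profile", "data.frame")
  out
}
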