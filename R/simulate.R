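#' Configuration for the PCR-cloning simulator
#'
#' Describes a branching-process model of PCR amplification from one or
#' several true allele templates: in every cycle each molecule in the
#' pool is copied with probability `efficiency`, each new copy inherits
#' its template's mutations and gains fresh misincorporations at
#' `Binomial(L, m_syn)` sites, and with probability `chimera_rate` a new
#' copy switches to a second uniformly chosen template at a uniform
#' breakpoint. After all cycles, `n_clones` molecules are sampled
#' without replacement (cloning) and truncated to random partial read
#' spans (sequencing reads shorter than the amplicon).
#'
#' @param alleles named character vector of aligned allele sequences
#'   (equal length; gaps allowed).
#' @param cycles number of pre-cloning PCR cycles (default 35).
#' @param efficiency probability a molecule is copied per cycle
#'   (default 1: perfect doubling).
#' @param m_syn per-site per-synthesis misincorporation probability.
#' @param deletion_fraction fraction of injected errors that are
#'   single-base deletions (default 0.03, matching the observed error
#'   spectrum of this method; the rest are substitutions).
#' @param transition_weight probability that an injected substitution is
#'   a transition. `NULL` (default) draws the new base uniformly from
#'   the three alternatives (transitions 1/3); 0.87 mimics the strong
#'   transition bias typical of Taq misincorporation.
#' @param chimera_rate per-new-copy template-switch probability
#'   (default 0; no quantitative value is anchored in real data, so
#'   this is a free parameter).
#' @param n_clones number of clones sampled from the final pool.
#' @param initial_copies initial template copy number per allele
#'   (recycled; default 10). Real reactions template many genomic
#'   copies; with at least 4 starting molecules per allele no single
#'   first-cycle misincorporation ("jackpot") can reach a majority of
#'   the final pool and corrupt the consensus.
#' @param min_read_length minimum partial read length (default 250).
#' @param truncation_prob probability that a read is truncated
#'   (default 0.18). Truncated reads get a uniform length in
#'   `[min_read_length, L]` and a uniform start, so both ends can be
#'   cut short; the rest span the whole amplicon. The default emulates
#'   clone reads of 253-761 bp averaging ~715 bp of a 761 bp region:
#'   mostly full-length with a minority of partial reads.
#' @param pool_cap molecule-pool cap (default 1e6): when the pool
#'   exceeds the cap it is uniformly thinned, which leaves the
#'   per-molecule lineage statistics unchanged while keeping memory
#'   desk-scale (2^35 molecules are unrepresentable).
#' @param engine `"branching"` simulates every molecule explicitly;
#'   `"lineage"` (efficiency-aware, chimera-free only) samples each
#'   clone's lineage directly — a random final-pool molecule has
#'   `Binomial(cycles, efficiency/(1+efficiency))` synthesis events —
#'   and is statistically equivalent when `n_clones` is much smaller
#'   than the pool; use it for large replicate studies.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(alleles, cycles = 35, efficiency = 1, m_syn = 1e-4,
                       deletion_fraction = 0.03, transition_weight = NULL,
                       chimera_rate = 0, n_clones = 82, initial_copies = 10,
                       min_read_length = 250, truncation_prob = 0.18,
                       pool_cap = 1e6,
                       engine = c("branching", "lineage")) {
  engine <- match.arg(engine)
  if (length(alleles) == 0L) stop("at least one allele sequence is required")
  if (is.null(names(alleles)) || any(!nzchar(names(alleles)))) {
    names(alleles) <- paste0("allele", seq_along(alleles))
  }
  alleles <- toupper(alleles)
  if (length(unique(nchar(alleles))) != 1L) {
    stop("alleles must be aligned to equal length")
  }
  bad <- setdiff(unique(unlist(strsplit(alleles, ""))), c("A", "C", "G", "T", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("alleles may contain only A,C,G,T,-: found %s",
      paste(sQuote(bad), collapse = ", ")))
  }
  probs <- c(efficiency = efficiency, m_syn = m_syn,
    deletion_fraction = deletion_fraction, chimera_rate = chimera_rate,
    truncation_prob = truncation_prob)
  if (any(probs < 0 | probs > 1)) {
    stop(sprintf("probabilities must be in [0,1]: %s",
      paste(names(probs)[probs < 0 | probs > 1], collapse = ", ")))
  }
  if (!is.null(transition_weight) &&
    (transition_weight < 0 || transition_weight > 1)) {
    stop("transition_weight must be in [0,1] or NULL")
  }
  if (cycles < 1 || cycles != floor(cycles)) stop("cycles must be a positive integer")
  if (n_clones < 1) stop("n_clones must be >= 1")
  L <- nchar(alleles[[1]])
  min_read_length <- min(min_read_length, L) # short amplicons: full reads
  if (min_read_length < 1) stop("min_read_length must be >= 1")
  initial_copies <- rep_len(as.integer(initial_copies), length(alleles))
  if (any(initial_copies < 1)) stop("initial_copies must be >= 1")
  if (engine == "lineage" && chimera_rate > 0) {
    stop("the lineage engine does not model chimeras; use engine = \"branching\"")
  }
  structure(
    list(
      alleles = alleles, cycles = as.integer(cycles),
      efficiency = efficiency, m_syn = m_syn,
      deletion_fraction = deletion_fraction,
      transition_weight = transition_weight,
      chimera_rate = chimera_rate, n_clones = as.integer(n_clones),
      initial_copies = initial_copies,
      min_read_length = as.integer(min_read_length),
      truncation_prob = truncation_prob,
      pool_cap = as.integer(pool_cap), engine = engine, L = L
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d allele(s) x %d bp, %d cycles (eff %g), m_syn %g, %d clones [%s]\n",
    length(x$alleles), x$L, x$cycles, x$efficiency, x$m_syn, x$n_clones,
    x$engine
  ))
  invisible(x)
}

TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# new base for a substitution at a site currently holding `base`
draw_substitution <- function(base, transition_weight) {
  if (is.null(transition_weight)) {
    return(sample(setdiff(c("A", "C", "G", "T"), base), 1L))
  }
  if (runif(1) < transition_weight) {
    TRANSITION_PARTNER[[base]]
  } else {
    sample(setdiff(c("A", "C", "G", "T"), c(base, TRANSITION_PARTNER[[base]])), 1L)
  }
}

# character vector of the template at the mutation-free level, from segments
segments_to_chars <- function(seg, allele_chars) {
  out <- character(ncol(allele_chars))
  for (r in seq_len(nrow(seg))) {
    out[seg[r, 2]:seg[r, 3]] <- allele_chars[seg[r, 1], seg[r, 2]:seg[r, 3]]
  }
  out
}

# inject k errors into a molecule given its current full sequence chars;
# returns updated mut matrix (col, obs) with later events overwriting
inject_errors <- function(mut, cur, cols, config) {
  for (col in cols) {
    base <- cur[col]
    if (base == "-") next # nothing to mis-copy at a gap
    obs <- if (runif(1) < config$deletion_fraction) {
      "-"
    } else {
      draw_substitution(base, config$transition_weight)
    }
    cur[col] <- obs
    mut <- mut[mut[, 1] != col, , drop = FALSE]
    mut <- rbind(mut, c(col, match(obs, c("A", "C", "G", "T", "-"))))
  }
  list(mut = mut, cur = cur)
}

empty_mut <- function() matrix(integer(0), ncol = 2)

#' Simulate a PCR-cloning experiment with full ground truth
#'
#' Runs the branching (or lineage-sampling) model described in
#' [sim_config()] and returns sampled clone sequences together with the
#' complete truth needed to validate every pipeline stage: source allele
#' (or chimera donors and breakpoints), every injected error, and the
#' number of synthesis events in each clone's lineage.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seed + config give identical
#'   output.
#' @return object of class `simulated_dataset`: list with `clones` (an
#'   [aligned_clone_set()]), `truth` (data frame: `clone_id`,
#'   `allele_id` — `"chimera"` for recombinants —, `donors`,
#'   `breakpoints`, `depth` (lineage synthesis events), `n_errors`,
#'   `errors` (string `col:ref>obs;...`), `read_start`, `read_end`),
#'   `config`, `pool_size`.
#' @export
simulate_pcr <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(as.integer(seed))
  if (config$engine == "branching") {
    simulate_branching(config)
  } else {
    simulate_lineage(config)
  }
}

allele_char_matrix <- function(config) {
  matrix(
    unlist(strsplit(config$alleles, ""), use.names = FALSE),
    nrow = length(config$alleles), byrow = TRUE,
    dimnames = list(names(config$alleles), NULL)
  )
}

simulate_branching <- function(config) {
  L <- config$L
  ach <- allele_char_matrix(config)
  n0 <- sum(config$initial_copies)
  seg <- vector("list", n0)
  mut <- vector("list", n0)
  depth <- integer(n0)
  i <- 0L
  for (a in seq_along(config$alleles)) {
    for (r in seq_len(config$initial_copies[a])) {
      i <- i + 1L
      seg[[i]] <- matrix(c(a, 1L, L), nrow = 1)
    }
  }
  for (cyc in seq_len(config$cycles)) {
    n <- length(depth)
    parents <- if (config$efficiency >= 1) {
      seq_len(n)
    } else {
      which(runif(n) < config$efficiency)
    }
    if (length(parents) == 0L) next
    child_seg <- seg[parents]
    child_mut <- mut[parents]
    child_depth <- depth[parents] + 1L
    # template switching
    if (config$chimera_rate > 0) {
      chim <- which(runif(length(parents)) < config$chimera_rate)
      for (c_i in chim) {
        partner <- sample.int(n, 1L)
        bp <- sample.int(L - 1L, 1L)
        s1 <- child_seg[[c_i]]
        s2 <- if (is.null(seg[[partner]])) NULL else seg[[partner]]
        left <- s1[s1[, 2] <= bp, , drop = FALSE]
        left[left[, 3] > bp, 3] <- bp
        right <- s2[s2[, 3] > bp, , drop = FALSE]
        right[right[, 2] <= bp, 2] <- bp + 1L
        child_seg[[c_i]] <- rbind(left, right)
        m1 <- child_mut[[c_i]]
        m2 <- mut[[partner]]
        keep1 <- if (is.null(m1)) empty_mut() else m1[m1[, 1] <= bp, , drop = FALSE]
        keep2 <- if (is.null(m2)) empty_mut() else m2[m2[, 1] > bp, , drop = FALSE]
        child_mut[[c_i]] <- rbind(keep1, keep2)
      }
    }
    # fresh misincorporations
    n_err <- rbinom(length(parents), L, config$m_syn)
    for (c_i in which(n_err > 0L)) {
      cols <- sample.int(L, n_err[c_i])
      cur <- segments_to_chars(child_seg[[c_i]], ach)
      m <- child_mut[[c_i]]
      if (!is.null(m) && nrow(m) > 0) {
        cur[m[, 1]] <- c("A", "C", "G", "T", "-")[m[, 2]]
      } else {
        m <- empty_mut()
      }
      upd <- inject_errors(m, cur, cols, config)
      child_mut[[c_i]] <- upd$mut
    }
    seg <- c(seg, child_seg)
    mut <- c(mut, child_mut)
    depth <- c(depth, child_depth)
    if (length(depth) > config$pool_cap) {
      keep <- sample.int(length(depth), config$pool_cap)
      seg <- seg[keep]
      mut <- mut[keep]
      depth <- depth[keep]
    }
  }
  pool_size <- length(depth)
  if (config$n_clones > pool_size) {
    stop(sprintf(
      "n_clones (%d) exceeds the final pool size (%d molecules)",
      config$n_clones, pool_size
    ))
  }
  picked <- sample.int(pool_size, config$n_clones)
  finalize_dataset(
    config, ach,
    seg[picked], mut[picked], depth[picked], pool_size
  )
}

simulate_lineage <- function(config) {
  L <- config$L
  ach <- allele_char_matrix(config)
  pool_size <- floor(sum(config$initial_copies) *
    (1 + config$efficiency)^config$cycles)
  if (config$n_clones > pool_size) {
    stop(sprintf(
      "n_clones (%d) exceeds the final pool size (%d molecules)",
      config$n_clones, pool_size
    ))
  }
  p_new <- config$efficiency / (1 + config$efficiency)
  n <- config$n_clones
  allele_idx <- sample.int(
    length(config$alleles), n,
    replace = TRUE, prob = config$initial_copies
  )
  depth <- rbinom(n, config$cycles, p_new)
  seg <- lapply(allele_idx, function(a) matrix(c(a, 1L, L), nrow = 1))
  mut <- vector("list", n)
  n_events <- rbinom(n, depth * L, config$m_syn)
  for (i in which(n_events > 0L)) {
    # sequential synthesis events: sites may repeat, later events win
    cols <- sample.int(L, n_events[i], replace = TRUE)
    cur <- ach[allele_idx[i], ]
    upd <- inject_errors(empty_mut(), cur, cols, config)
    mut[[i]] <- upd$mut
  }
  finalize_dataset(config, ach, seg, mut, depth, pool_size)
}

finalize_dataset <- function(config, ach, seg, mut, depth, pool_size) {
  L <- config$L
  n <- length(depth)
  states <- c("A", "C", "G", "T", "-")
  ids <- sprintf("clone%03d", seq_len(n))
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    template <- segments_to_chars(seg[[i]], ach)
    s <- template
    m <- mut[[i]]
    if (!is.null(m) && nrow(m) > 0) s[m[, 1]] <- states[m[, 2]]
    len <- if (config$min_read_length >= L ||
      runif(1) >= config$truncation_prob) {
      L
    } else {
      sample(config$min_read_length:L, 1L)
    }
    start <- if (len >= L) 1L else sample.int(L - len + 1L, 1L)
    end <- start + len - 1L
    out <- rep("-", L)
    out[start:end] <- s[start:end]
    seqs[i] <- paste(out, collapse = "")
    in_span <- if (!is.null(m) && nrow(m) > 0) {
      m[m[, 1] >= start & m[, 1] <= end, , drop = FALSE]
    } else {
      empty_mut()
    }
    err_str <- if (nrow(in_span) > 0) {
      ord <- order(in_span[, 1])
      paste(sprintf(
        "%d:%s>%s", in_span[ord, 1],
        template[in_span[ord, 1]], states[in_span[ord, 2]]
      ), collapse = ";")
    } else {
      ""
    }
    is_chim <- nrow(seg[[i]]) > 1L
    truth[[i]] <- data.frame(
      clone_id = ids[i],
      allele_id = if (is_chim) "chimera" else names(config$alleles)[seg[[i]][1, 1]],
      donors = paste(names(config$alleles)[seg[[i]][, 1]], collapse = ","),
      breakpoints = if (is_chim) {
        paste(seg[[i]][-nrow(seg[[i]]), 3], collapse = ",")
      } else {
        ""
      },
      depth = depth[i],
      n_errors = nrow(in_span),
      errors = err_str,
      read_start = start, read_end = end,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      clones = aligned_clone_set(seqs, ids = ids),
      truth = do.call(rbind, truth),
      config = config,
      pool_size = pool_size
    ),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d clones x %d bp from %d allele(s); pool %g; %d chimera(s)\n",
    x$clones$n, x$clones$width, length(x$config$alleles), x$pool_size,
    sum(x$truth$allele_id == "chimera")
  ))
  invisible(x)
}

#' Analytic expected per-site error frequency
#'
#' Under perfect doubling the mean number of synthesis events in a
#' random final-pool lineage is `cycles / 2`, so the expected per-site
#' error frequency in sampled clones is `m_syn * cycles / 2` — the
#' rearrangement `f = m d / 2` of the per-duplication rate formula. No
#' closed form is supplied for `efficiency < 1`; use simulation there.
#'
#' @param config a [sim_config()].
#' @return expected per-site error frequency.
#' @export
expected_error_frequency <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$efficiency < 1) {
    stop("analytic prediction requires efficiency = 1; use simulation instead")
  }
  config$m_syn * config$cycles / 2
}

#' Confusion summary of a pipeline run against simulator ground truth
#'
#' Maps each recovered group to the true allele held by the majority of
#' its (truth) non-chimeric members, then counts alleles recovered,
#' clone-membership accuracy, error-only clones wrongly accepted as new
#' alleles by the threshold, and (when chimera calls are supplied)
#' chimera detection performance.
#'
#' A true allele is recovered when some group maps to it;
#' `consensus_exact` additionally records whether a mapping group's
#' consensus matches the allele at every covered, untied column (a
#' stricter condition that first-cycle jackpot mutations can break).
#' A false allele is a non-chimeric clone whose true allele equals its
#' group's allele (so only misincorporation separates it from the
#' consensus) and whose deviation count reaches the threshold `k_star`.
#'
#' @param dataset a [simulate_pcr()] result.
#' @param grouping a [cut_groups()] result on `dataset$clones`.
#' @param thresholds a [polymorphism_threshold()] result (optional).
#' @param chimera_calls a [flag_chimeras()] result (optional).
#' @return list with `n_true_alleles`, `recovered` (named logical),
#'   `consensus_exact` (named logical),
#'   `n_recovered`, `membership_accuracy`, `n_misassigned`,
#'   `n_ungrouped_real`, `n_false_alleles`, `false_allele_ids`,
#'   `accepted_ids`, and `chimera` (list with `n_true`, `n_flagged`,
#'   `tp`, `fn`, `fp`) when calls are given.
#' @export
evaluate_recovery <- function(dataset, grouping, thresholds = NULL,
                              chimera_calls = NULL) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  stopifnot(inherits(grouping, "grouping_result"))
  truth <- dataset$truth
  allele_names <- names(dataset$config$alleles)
  ach <- allele_char_matrix(dataset$config)
  # group -> majority true allele of non-chimeric members
  group_allele <- vapply(names(grouping$groups), function(g) {
    members <- grouping$groups[[g]]
    tt <- truth$allele_id[match(members, truth$clone_id)]
    tt <- tt[tt != "chimera"]
    if (length(tt) == 0L) {
      return(NA_character_)
    }
    names(sort(table(tt), decreasing = TRUE))[1]
  }, character(1))
  recovered <- setNames(rep(FALSE, length(allele_names)), allele_names)
  consensus_exact <- recovered
  for (g in names(grouping$groups)) {
    al <- group_allele[[g]]
    if (is.na(al)) next
    recovered[al] <- TRUE
    cp <- grouping$consensus[[g]]
    covered <- !cp$tie_flag & colSums(cp$counts) > 0
    if (all(cp$majority[covered] == ach[al, covered])) {
      consensus_exact[al] <- TRUE
    }
  }
  real <- truth[truth$allele_id != "chimera", ]
  member_group <- grouping$membership$group_id[
    match(real$clone_id, grouping$membership$clone_id)
  ]
  grouped <- member_group != "ungrouped"
  correct <- grouped & group_allele[member_group] == real$allele_id
  accuracy <- if (sum(grouped) > 0) sum(correct, na.rm = TRUE) / sum(grouped) else NA_real_
  # threshold decisions: deviations of each grouped clone from its
  # group consensus
  accepted_ids <- character(0)
  false_ids <- character(0)
  if (!is.null(thresholds) && thresholds$attainable) {
    for (g in names(grouping$groups)) {
      members <- grouping$groups[[g]]
      if (length(members) < 2L) next
      sub <- subset_clones(dataset$clones, members)
      k <- deviations_per_clone(sub, call_deviations(sub, grouping$consensus[[g]]))
      acc <- names(k)[k >= thresholds$k_star]
      accepted_ids <- c(accepted_ids, acc)
      tt <- truth$allele_id[match(acc, truth$clone_id)]
      false_ids <- c(false_ids, acc[tt != "chimera" & tt == group_allele[[g]]])
    }
  }
  out <- list(
    n_true_alleles = length(allele_names),
    recovered = recovered,
    consensus_exact = consensus_exact,
    n_recovered = sum(recovered),
    membership_accuracy = accuracy,
    n_misassigned = sum(grouped & !correct, na.rm = TRUE),
    n_ungrouped_real = sum(!grouped),
    n_false_alleles = length(false_ids),
    false_allele_ids = false_ids,
    accepted_ids = accepted_ids
  )
  if (!is.null(chimera_calls)) {
    truth_chim <- truth$clone_id[truth$allele_id == "chimera"]
    called <- chimera_calls$clone_id[chimera_calls$is_chimera]
    out$chimera <- list(
      n_true = length(truth_chim),
      n_flagged = length(called),
      tp = length(intersect(truth_chim, called)),
      fn = length(setdiff(truth_chim, called)),
      fp = length(setdiff(called, truth_chim))
    )
  }
  out
}

#' Write a simulated dataset to disk
#'
#' Clones as aligned FASTA, ground truth as TSV, configuration echoed as
#' JSON, byte-identical for identical seed and configuration.
#'
#' @param dataset a [simulate_pcr()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_aligned_fasta(dataset$clones, file.path(dir, "clones.fasta"))
  write_tsv_report(dataset$truth, file.path(dir, "truth.tsv"))
  cfg <- dataset$config
  cfg$alleles <- as.list(cfg$alleles)
  jsonlite::write_json(
    unclass(cfg), file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
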