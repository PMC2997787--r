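test_that("pairwise_distances counts events with gap-run collapsing", {
  acs <- aligned_clone_set(c(a = "ACGT", b = "ACGT"))
  expect_equal(pairwise_distances(acs)$d["a", "b"], 0)
  acs2 <- aligned_clone_set(c(a = "ACGT", b = "ACGA"))
  expect_equal(pairwise_distances(acs2)$d["a", "b"], 1)
  # one interior gap run of length 1 -> 1 event
  acs3 <- aligned_clone_set(c(a = "ACG-T", b = "ACGAT"))
  expect_equal(pairwise_distances(acs3)$d["a", "b"], 1)
  # a 3-column interior gap run is still one event
  acs4 <- aligned_clone_set(c(a = "AC---GTA", b = "ACTTAGTA"))
  expect_equal(pairwise_distances(acs4)$d["a", "b"], 1)
  # two separate runs + a substitution
  acs5 <- aligned_clone_set(c(a = "A-CG-TAC", b = "AACGATAG"))
  expect_equal(pairwise_distances(acs5)$d["a", "b"], 3)
  # terminal gaps restrict the scored overlap instead of counting
  acs6 <- aligned_clone_set(c(a = "--CGTA", b = "ACCGT-"))
  dm6 <- pairwise_distances(acs6)
  expect_equal(dm6$d["a", "b"], 0)
  expect_equal(dm6$n_scored["a", "b"], 3)
  # metric sanity on a random set
  set.seed(5)
  acs7 <- alignment_with_errors(
    random_seq(80), 6,
    errors = data.frame(
      clone = sample(1:6, 10, TRUE), column = sample(2:79, 10),
      state = sample(BASES, 10, TRUE)
    )
  )
  dm7 <- pairwise_distances(acs7)$d
  expect_true(all(diag(dm7) == 0))
  expect_identical(dm7, t(dm7))
  expect_true(all(dm7 >= 0))
})

test_that("upgma reproduces hand-derived average-linkage dendrograms", {
  # two clones at distance 5 merge at height 2.5
  two <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- upgma(two)
  expect_equal(t2$height, 2.5)
  # block fixture: merges at 1, 1, 60
  tree <- upgma(pairwise_distances(block_fixture()))
  expect_equal(sort(tree$height), c(1, 1, 60))
  # all-zero matrix: all merges at height 0
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(upgma(z)$height, c(0, 0))
  # ties broken by lexicographically smallest member id
  tie <- matrix(4, 3, 3, dimnames = list(c("c", "a", "b"), c("c", "a", "b")))
  diag(tie) <- 0
  tt <- upgma(tie)
  first_pair <- sort(tt$labels[-tt$merge[1, ]])
  expect_identical(first_pair, c("a", "b"))
})

test_that("upgma agrees with average-linkage hclust on random matrices", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    m <- matrix(runif(n * n, 1, 50), n)
    m <- m + t(m)
    diag(m) <- 0
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    ours <- upgma(m)
    ref <- hclust(as.dist(m), method = "average")
    expect_equal(ours$height, ref$height / 2, tolerance = 1e-10)
    expect_true(all(diff(ours$height) >= -1e-12)) # monotone merges
    # same partitions at a mid cut
    h <- stats::median(ref$height)
    a <- cutree(ours, h = h / 2)
    b <- cutree(ref, h = h)
    expect_identical(
      unname(split(names(a), a)[order(vapply(split(names(a), a), min, ""))],
      ),
      unname(split(names(b), b)[order(vapply(split(names(b), b), min, ""))])
    )
  }
})

test_that("cut_groups partitions clones and builds group consensus", {
  blocks <- block_fixture()
  dm <- pairwise_distances(blocks)
  gr <- cut_groups(blocks, tree = upgma(dm), cut_height = 50,
    min_group_size = 2, dm = dm
  )
  expect_identical(length(gr$groups), 2L)
  expect_setequal(
    vapply(gr$groups, paste, character(1), collapse = "+"),
    c("a1+a2", "b1+b2")
  )
  expect_equal(gr$within, 2)
  expect_equal(gr$between, 120)
  # group consensus regenerates zero deviations for an identical clone
  cp <- gr$consensus[[1]]
  probe <- aligned_clone_set(c(p1 = cp$sequence, p2 = cp$sequence))
  expect_identical(nrow(call_deviations(probe, build_consensus(probe))), 0L)
  # cut at 0 on distinct clones: all singletons -> ungrouped at default size
  gr0 <- cut_groups(blocks, tree = upgma(dm), cut_height = 0, dm = dm)
  expect_identical(length(gr0$groups), 0L)
  expect_setequal(gr0$ungrouped, blocks$ids)
  # every clone is in exactly one of {a group, ungrouped}
  all_ids <- c(unlist(gr$groups, use.names = FALSE), gr$ungrouped)
  expect_setequal(all_ids, blocks$ids)
  expect_identical(anyDuplicated(all_ids), 0L)
})

test_that("grouping recovers simulated alleles at the default cut", {
  a1 <- random_seq(715, seed = 21)
  a2 <- diverge_allele(a1, 150, seed = 22)
  correct <- 0
  for (s in 1:4) {
    cfg <- sim_config(c(alA = a1, alB = a2),
      cycles = 10, m_syn = 2.7e-4,
      n_clones = 50, engine = "branching"
    )
    ds <- simulate_pcr(cfg, seed = s)
    dm <- pairwise_distances(ds$clones)
    gr <- cut_groups(ds$clones, tree = upgma(dm), cut_height = 50, dm = dm)
    ev <- evaluate_recovery(ds, gr)
    correct <- correct +
      (length(gr$groups) == 2 && ev$membership_accuracy == 1)
  }
  expect_identical(correct, 4)
})

test_that("newick export preserves topology and merge heights", {
  tree <- upgma(pairwise_distances(block_fixture()))
  nwk <- write_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a1", "a2", "b1", "b2"))
  depths <- ape::node.depth.edgelength(phy)
  root_height <- max(depths)
  expect_equal(root_height, 60) # deepest merge at height 60
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  expect_identical(readLines(path), nwk)
})

test_that("flag_chimeras detects constructed recombinants", {
  a1 <- random_seq(1800, seed = 31)
  a2 <- diverge_allele(a1, 200, seed = 32)
  group_clones <- c(
    setNames(rep(a1, 4), paste0("ga", 1:4)),
    setNames(rep(a2, 4), paste0("gb", 1:4))
  )
  chimera <- paste0(substr(a1, 1, 900), substr(a2, 901, 1800))
  acs <- aligned_clone_set(c(group_clones,
    chim = chimera, pure = a1
  ))
  dm <- pairwise_distances(acs)
  gr <- cut_groups(acs, tree = upgma(dm), cut_height = 50,
    min_group_size = 3, dm = dm
  )
  expect_identical(length(gr$groups), 2L)
  calls <- flag_chimeras(acs, gr, window = 100, min_diagnostic_sites = 5,
    clone_ids = c("chim", "pure")
  )
  expect_true(calls$is_chimera[calls$clone_id == "chim"])
  expect_false(calls$is_chimera[calls$clone_id == "pure"])
  bp <- as.integer(strsplit(
    calls$breakpoints[calls$clone_id == "chim"], ","
  )[[1]])
  expect_length(bp, 1)
  expect_lt(abs(bp - 900), 101) # breakpoint within one window
})

test_that("flag_chimeras is not applicable below two groups", {
  tpl <- random_seq(300, seed = 41)
  acs <- alignment_with_errors(tpl, 5)
  dm <- pairwise_distances(acs)
  gr <- cut_groups(acs, tree = upgma(dm), cut_height = 50, dm = dm)
  expect_identical(length(gr$groups), 1L)
  calls <- flag_chimeras(acs, gr)
  expect_false(any(calls$is_chimera))
  expect_true(all(calls$n_segments == 0L))
})

test_that("weak diagnostic support never calls a chimera", {
  a1 <- random_seq(400, seed = 51)
  a2 <- diverge_allele(a1, 120, seed = 52)
  acs <- aligned_clone_set(c(
    setNames(rep(a1, 3), paste0("ga", 1:3)),
    setNames(rep(a2, 3), paste0("gb", 1:3)),
    probe = a1
  ))
  dm <- pairwise_distances(acs)
  gr <- cut_groups(acs, tree = upgma(dm), cut_height = 50, dm = dm)
  # demand more support than any segment can have
  calls <- flag_chimeras(acs, gr,
    window = 100,
    min_diagnostic_sites = 1000, clone_ids = "probe"
  )
  expect_false(calls$is_chimera)
})

test_that("sliding_window_profile computes per-site per-sequence rates", {
  tpl <- random_seq(200, seed = 61)
  clean <- alignment_with_errors(tpl, 5)
  prof0 <- sliding_window_profile(clean, window = 100, step = 25)
  expect_true(all(prof0$rate == 0))
  expect_identical(nrow(prof0), as.integer((200 - 100) / 25 + 1))
  # one substitution at column 10, 5 clones fully covering
  v <- strsplit(tpl, "")[[1]]
  err <- data.frame(
    clone = 1, column = 10,
    state = setdiff(BASES, v[10])[1]
  )
  one <- alignment_with_errors(tpl, 5, err)
  prof1 <- sliding_window_profile(one, window = 100, step = 25)
  covered <- prof1$start <= 10 & prof1$end >= 10
  expect_equal(prof1$rate[covered], rep(1 / 500, sum(covered)))
  expect_equal(prof1$rate[!covered], rep(0, sum(!covered)))
  expect_error(sliding_window_profile(one, window = 500), "width")
  expect_error(sliding_window_profile(one, window = 50, step = 0), "step")
})

test_that("uniform simulated errors show no positional bias", {
  # chi-square uniformity of deviations across non-overlapping windows
  a1 <- random_seq(715, seed = 71)
  nonsig <- 0
  for (s in 1:20) {
    cfg <- sim_config(c(al = a1),
      cycles = 20, m_syn = 1.62e-4, n_clones = 82,
      truncation_prob = 0, engine = "lineage"
    )
    ds <- simulate_pcr(cfg, seed = s)
    prof <- sliding_window_profile(ds$clones, window = 65, step = 65)
    o <- prof$substitutions
    if (sum(o) == 0) {
      nonsig <- nonsig + 1
      next
    }
    p <- suppressWarnings(
      stats::chisq.test(o, p = prof$sites / sum(prof$sites))$p.value
    )
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig, 18) # >= 90% of replicates non-significant
})
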