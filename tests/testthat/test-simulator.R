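test_that("sim_config validates probabilities, alleles and engine limits", {
  a <- random_seq(100, seed = 1)
  expect_error(sim_config(character(0)), "at least one")
  expect_error(sim_config(c(a, substr(a, 1, 50))), "equal length")
  expect_error(sim_config(c(x = "ACGTN")), "A,C,G,T")
  expect_error(sim_config(c(x = a), m_syn = 1.5), "\\[0,1\\]")
  expect_error(sim_config(c(x = a), cycles = 0), "cycles")
  expect_error(
    sim_config(c(x = a), chimera_rate = 0.1, engine = "lineage"),
    "lineage engine"
  )
  cfg <- sim_config(c(x = a), cycles = 5, n_clones = 10)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$L, 100L)
})

test_that("error-free simulation returns exact allele copies", {
  a <- random_seq(200, seed = 2)
  cfg <- sim_config(c(al1 = a),
    cycles = 6, m_syn = 0, n_clones = 20,
    initial_copies = 1, engine = "branching"
  )
  ds <- simulate_pcr(cfg, seed = 1)
  expect_identical(ds$pool_size, 64L) # perfect doubling from one copy
  expect_true(all(ds$truth$n_errors == 0))
  expect_true(all(ds$truth$allele_id == "al1"))
  spans <- read_spans(ds$clones)
  for (i in seq_len(ds$clones$n)) {
    sp <- spans[i, ]
    expect_identical(
      paste(ds$clones$mat[i, sp[1]:sp[2]], collapse = ""),
      substr(a, sp[1], sp[2])
    )
  }
})

test_that("simulation is deterministic and truth reconstructs each clone", {
  a1 <- random_seq(300, seed = 3)
  a2 <- diverge_allele(a1, 60, seed = 4)
  cfg <- sim_config(c(alA = a1, alB = a2),
    cycles = 8, m_syn = 1e-3,
    n_clones = 30, engine = "branching"
  )
  d1 <- simulate_pcr(cfg, seed = 5)
  d2 <- simulate_pcr(cfg, seed = 5)
  expect_identical(as.character(d1$clones), as.character(d2$clones))
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_pcr(cfg, seed = 6)
  expect_false(identical(as.character(d1$clones), as.character(d3$clones)))
  # every non-chimeric clone = source allele + recorded errors, in span
  alleles <- c(alA = a1, alB = a2)
  for (i in which(d1$truth$allele_id != "chimera")) {
    tr <- d1$truth[i, ]
    v <- strsplit(alleles[[tr$allele_id]], "")[[1]]
    if (nzchar(tr$errors)) {
      for (e in strsplit(tr$errors, ";")[[1]]) {
        parts <- regmatches(e, regexec("^(\\d+):(.)>(.)$", e))[[1]]
        col <- as.integer(parts[2])
        expect_identical(v[col], parts[3]) # recorded ref matches allele
        v[col] <- parts[4]
      }
    }
    got <- d1$clones$mat[match(tr$clone_id, d1$clones$ids), ]
    expect_identical(
      paste(got[tr$read_start:tr$read_end], collapse = ""),
      paste(v[tr$read_start:tr$read_end], collapse = "")
    )
    expect_true(all(got[setdiff(seq_len(300), tr$read_start:tr$read_end)] == "-"))
  }
})

test_that("oversampling the pool fails with the pool size named", {
  a <- random_seq(100, seed = 7)
  cfg <- sim_config(c(al = a),
    cycles = 3, n_clones = 100,
    initial_copies = 1, engine = "branching"
  )
  expect_error(simulate_pcr(cfg, seed = 1), "pool size \\(8")
})

test_that("chimera_rate = 0 yields no chimeras; > 0 records breakpoints", {
  a1 <- random_seq(400, seed = 8)
  a2 <- diverge_allele(a1, 100, seed = 9)
  cfg0 <- sim_config(c(alA = a1, alB = a2),
    cycles = 8, m_syn = 1e-4,
    n_clones = 40, engine = "branching"
  )
  ds0 <- simulate_pcr(cfg0, seed = 2)
  expect_identical(sum(ds0$truth$allele_id == "chimera"), 0L)
  cfg1 <- sim_config(c(alA = a1, alB = a2),
    cycles = 8, m_syn = 0,
    chimera_rate = 0.2, n_clones = 60, engine = "branching"
  )
  ds1 <- simulate_pcr(cfg1, seed = 3)
  chim <- ds1$truth[ds1$truth$allele_id == "chimera", ]
  expect_gt(nrow(chim), 0)
  expect_true(all(nzchar(chim$breakpoints)))
  expect_true(all(vapply(strsplit(chim$donors, ","), length, 1L) >= 2))
})

test_that("mean lineage depth approaches cycles/2 under perfect doubling", {
  a <- random_seq(50, seed = 10)
  cfg <- sim_config(c(al = a),
    cycles = 15, m_syn = 0, n_clones = 2000,
    initial_copies = 4, min_read_length = 50, engine = "branching"
  )
  ds <- simulate_pcr(cfg, seed = 4)
  expect_lt(abs(mean(ds$truth$depth) - 7.5) / 7.5, 0.05)
})

test_that("lineage and branching engines agree on error statistics", {
  a <- random_seq(400, seed = 11)
  mean_err <- function(engine, seeds) {
    vals <- vapply(seeds, function(s) {
      cfg <- sim_config(c(al = a),
        cycles = 10, m_syn = 5e-4, n_clones = 50,
        truncation_prob = 0, engine = engine
      )
      mean(simulate_pcr(cfg, seed = s)$truth$n_errors)
    }, numeric(1))
    mean(vals)
  }
  mb <- mean_err("branching", 1:6)
  ml <- mean_err("lineage", 1:6)
  expected <- 400 * 5e-4 * 10 / 2 # L * m_syn * d/2 = 1
  expect_lt(abs(mb - expected) / expected, 0.25)
  expect_lt(abs(ml - expected) / expected, 0.25)
})

test_that("expected_error_frequency is analytic only for perfect doubling", {
  a <- random_seq(100, seed = 12)
  cfg <- sim_config(c(al = a), cycles = 35, m_syn = 1e-4)
  expect_equal(expected_error_frequency(cfg), 1.75e-3)
  cfg0 <- sim_config(c(al = a), cycles = 35, m_syn = 0)
  expect_equal(expected_error_frequency(cfg0), 0)
  cfg_e <- sim_config(c(al = a), cycles = 35, m_syn = 1e-4, efficiency = 0.8)
  expect_error(expected_error_frequency(cfg_e), "efficiency = 1")
})

test_that("m-hat = 2 f-hat / d closes the loop on m_syn", {
  a <- random_seq(715, seed = 13)
  f_hat <- vapply(1:25, function(s) {
    cfg <- sim_config(c(al = a),
      cycles = 20, m_syn = 1e-4, n_clones = 82,
      engine = "lineage"
    )
    ds <- simulate_pcr(cfg, seed = s)
    nrow(call_deviations(ds$clones)) / comparable_bases(ds$clones)
  }, numeric(1))
  m_hat <- 2 * mean(f_hat) / 20
  expect_lt(abs(m_hat - 1e-4) / 1e-4, 0.2) # scaled-down Monte-Carlo check
})

test_that("per-clone error counts fit the binomial model", {
  # scaled-down version of the 100-seed uniformity property: the GOF
  # test should rarely reject its own generating model
  a <- random_seq(715, seed = 17)
  rejections <- 0
  for (s in 1:40) {
    cfg <- sim_config(c(al = a),
      cycles = 20, m_syn = 1.62e-4, n_clones = 82,
      truncation_prob = 0, engine = "lineage"
    )
    ds <- simulate_pcr(cfg, seed = s)
    k <- deviations_per_clone(ds$clones)
    model <- binom_error_model(715, expected_error_frequency(cfg))
    obs <- tabulate(k + 1L, nbins = max(k) + 1L)
    ed <- expected_distribution(82, model, k_max = max(k))
    g <- gof_chi_square(obs, ed$raw, pooling = "tail")
    rejections <- rejections + (g$p_value < 0.05)
  }
  expect_lte(rejections / 40, 0.10)
})

test_that("evaluate_recovery is perfect on error-free data", {
  a1 <- random_seq(400, seed = 14)
  a2 <- diverge_allele(a1, 120, seed = 15)
  cfg <- sim_config(c(alA = a1, alB = a2),
    cycles = 8, m_syn = 0,
    n_clones = 40, engine = "branching"
  )
  ds <- simulate_pcr(cfg, seed = 6)
  dm <- pairwise_distances(ds$clones)
  gr <- cut_groups(ds$clones, tree = upgma(dm), cut_height = 50, dm = dm)
  thr <- polymorphism_threshold(
    40, binom_error_model(400, paper_rate), 0.05, "bonferroni_tail"
  )
  ev <- evaluate_recovery(ds, gr, thr)
  expect_identical(ev$n_recovered, 2L)
  expect_true(all(ev$consensus_exact))
  expect_equal(ev$membership_accuracy, 1)
  expect_identical(ev$n_false_alleles, 0L)
})

test_that("read spans honour min length and truncation settings", {
  a <- random_seq(500, seed = 16)
  cfg <- sim_config(c(al = a),
    cycles = 8, m_syn = 0, n_clones = 60,
    min_read_length = 250, truncation_prob = 1, engine = "branching"
  )
  ds <- simulate_pcr(cfg, seed = 7)
  len <- ds$truth$read_end - ds$truth$read_start + 1
  expect_true(all(len >= 250 & len <= 500))
  expect_gt(length(unique(len)), 1)
  cfg_full <- sim_config(c(al = a),
    cycles = 8, m_syn = 0, n_clones = 20,
    truncation_prob = 0, engine = "branching"
  )
  ds_full <- simulate_pcr(cfg_full, seed = 8)
  expect_true(all(ds_full$truth$read_start == 1 & ds_full$truth$read_end == 500))
})
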