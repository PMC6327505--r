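test_that("generators are pure functions of (config, seed)", {
  d1 <- generate_evolution_dataset(default_scenario(seed = 4))
  d2 <- generate_evolution_dataset(default_scenario(seed = 4))
  expect_identical(d1, d2)
  d3 <- generate_evolution_dataset(default_scenario(seed = 5))
  expect_false(identical(d1$pyroseq$reads, d3$pyroseq$reads))

  p1 <- generate_promoters(5, 120, seed = 8)
  expect_identical(p1, generate_promoters(5, 120, seed = 8))
  u1 <- generate_uptake_data(10, 20, seed = 8)
  expect_identical(u1, generate_uptake_data(10, 20, seed = 8))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_evolution_dataset(default_scenario()))
  expect_identical(runif(1), before)
})

test_that("default scenario reproduces the narrative milestones", {
  ds <- generate_evolution_dataset(default_scenario())
  f <- ds$fractions$fraction
  g <- ds$fractions$generations
  # variant passes the 1% detection threshold at generation 70
  expect_true(all(f[g < 70] == 0))
  expect_gte(f[g == 80], 0.01)
  # dominant (>= 50%) by generation 210
  expect_gte(f[g == 200], 0.5)
  expect_lt(f[g == 140], 0.5)
  # over 97% of the population at generation 445
  expect_gte(f[g == 440], 0.97)
  # truth record is sufficient to rebuild the scenario
  expect_named(ds$truth, c("parent", "mutant", "chemostat", "emergence",
                           "stoich_parent", "stoich_mutant", "cv", "depth",
                           "thr_share", "seed"))
})

test_that("vanishing noise: observed fractions and metabolites match truth", {
  sc <- scenario_config(cv = 0, depth = 1e6, thr_share = 0)
  ds <- generate_evolution_dataset(sc)
  obs <- ds$pyroseq[ds$pyroseq$variant == "ile", "fraction"]
  expect_lt(max(abs(obs - ds$fractions$fraction)), 0.002)
  # metabolite mixture interpolates the two strains' stoichiometries:
  # lactate:acetate ratio slides from ~16 (parent) to ~7 (evolved)
  lac <- ds$metabolites[ds$metabolites$metabolite == "lactate", "conc_mM"]
  ace <- ds$metabolites[ds$metabolites$metabolite == "acetate", "conc_mM"]
  expect_equal(lac[1] / ace[1], 16, tolerance = 1e-6)
  expect_equal(tail(lac, 1) / tail(ace, 1), 7, tolerance = 0.01)
  expect_identical(fermentation_metrics(lac[1], ace[1])$mode,
                   "homolactic-dominant")
  expect_identical(fermentation_metrics(tail(lac, 1),
                                        tail(ace, 1))$mode,
                   "mixed-acid-shifted")
  # pyruvate overflow appears as the evolved strain takes over
  pyr <- ds$metabolites[ds$metabolites$metabolite == "pyruvate", "conc_mM"]
  expect_equal(pyr[1], 0)
  expect_gt(tail(pyr, 1), 0)
  # per-strain stoichiometries are themselves redox-closed modes
  for (st in list(ds$truth$stoich_parent, ds$truth$stoich_mutant)) {
    fs <- fermentation_stoichiometry(st[["lactate"]], st[["acetate"]],
                                     st[["ethanol"]], st[["formate"]],
                                     st[["pyruvate"]])
    expect_equal(fs$nadh_balance, 0, tolerance = 1e-9)
    expect_equal(fs$carbon_balance, 6, tolerance = 1e-9)
  }
})

test_that("pyrosequencing counts are multinomial with validation", {
  expect_identical(generate_pyroseq_counts(c(wt = 1, a = 0, b = 0), 500,
                                           seed = 1),
                   c(wt = 500, a = 0, b = 0))
  cnt <- generate_pyroseq_counts(c(0.5, 0.5), 10000, seed = 2)
  expect_identical(sum(cnt), 10000)
  # binomial SD oracle: within 3 SD of 0.5
  expect_lt(abs(cnt[1] / 10000 - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(generate_pyroseq_counts(c(0.5, 0.5), 0), "depth")
  expect_error(generate_pyroseq_counts(c(-0.1, 1.1), 10), "negative")
  expect_error(generate_pyroseq_counts(c(0.5, 0.4), 10), "sum to 1")
})

test_that("promoter generator plants sites exactly and validates overlaps", {
  pl <- data.frame(seq = c(1, 2), site = c("TGAAAACGATTACA",
                                           "TGTTATCGCTTTCA"),
                   start = c(10, 40), strand = c("+", "-"))
  pr <- generate_promoters(3, 80, planted = pl, seed = 21)
  hits <- scan_cre_sites(pr$sequences, max_mismatch = 0)
  # every planted site is recovered at its planted position and strand
  for (i in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[i, ]
    found <- hits[hits$seq_id == tr$seq_id & hits$start == tr$start &
                    hits$strand == tr$strand, ]
    expect_identical(nrow(found), 1L)
    expect_identical(found$site_seq, tr$site)
  }
  # planted "+" site occupies the stated substring verbatim
  expect_identical(substr(pr$sequences[["promoter_001"]], 11, 24),
                   "TGAAAACGATTACA")
  expect_error(generate_promoters(2, 80, planted = data.frame(
    seq = 1, site = "TGAAAACGATTACA", start = 70)), "fit")
  expect_error(generate_promoters(2, 80, planted = data.frame(
    seq = c(1, 1), site = c("TGAAAACGATTACA", "TGAAAACGATTACA"),
    start = c(10, 20))), "overlap")
  # GC content control
  gcfrac <- function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }
  hi <- generate_promoters(20, 500, gc = 0.7, seed = 5)
  expect_equal(mean(vapply(hi$sequences, gcfrac, 0)), 0.7, tolerance = 0.02)
})

test_that("background false-hit rate matches the binomial expectation", {
  # 9 fixed consensus positions at GC 0.5: per strand-window p = 4^-9
  n_seq <- 12
  len <- 100
  n_seeds <- 40
  windows <- (len - 14 + 1) * 2 * n_seq * n_seeds
  p <- 0.25^9
  hits <- 0
  for (s in seq_len(n_seeds)) {
    pr <- generate_promoters(n_seq, len, seed = 3000 + s)
    hits <- hits + nrow(scan_cre_sites(pr$sequences, max_mismatch = 0))
  }
  expect_lt(abs(hits - windows * p), 3 * sqrt(windows * p * (1 - p)) + 1)
})

test_that("uptake generator round-trips through the kinetics fit", {
  d0 <- generate_uptake_data(10, 20, cv = 0, replicates = 2, seed = 1)
  expect_equal(d0$data$v, 10 * d0$data$S / (20 + d0$data$S))
  ft <- fit_uptake_kinetics(d0$data$S, d0$data$v)
  expect_equal(ft$Vmax, 10, tolerance = 1e-6)
  expect_equal(ft$Km, 20, tolerance = 1e-6)
  expect_error(generate_uptake_data(10, 20, S_levels = c(-1, 5)), "positive")
})
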