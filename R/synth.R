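## Seeded generators for every input the analysis consumes: wash-in
## evolution datasets (biomass, metabolites, pyrosequencing counts),
## promoter sequences with planted cre sites, and Michaelis-Menten uptake
## curves. All generators are pure functions of (config, seed) and ship a
## truth record sufficient to score any downstream estimate.

#' Scenario configuration for the synthetic evolution experiment
#'
#' Defaults describe a glucose-limited chemostat at D = 0.5 h^-1 with 25 mM
#' glucose feed, a parent strain (mu_max 0.7 h^-1, K_M 0.1 mM) and an
#' evolved strain whose mu_max dropped towards D (0.55 h^-1) while its Monod
#' constant dropped tenfold (0.01 mM), equal biomass yields, and a variant
#' that emerges at 1% frequency at generation 70 (the detection threshold of
#' the fraction assay). Sampling every 20 generations to generation 445;
#' lognormal concentration noise (CV 0.05) and multinomial pyrosequencing
#' depth 500.
#'
#' @param parent,mutant [strain_params()] objects.
#' @param chemostat A [chemostat_config()].
#' @param emergence An [emergence_spec()].
#' @param sample_generations Generation grid.
#' @param cv Concentration coefficient of variation (multiplicative
#'   lognormal), >= 0.
#' @param depth Pyrosequencing reads per sample, >= 1.
#' @param thr_share Share of the mutant population carrying the minor
#'   (Thr-like) codon variant rather than the major (Ile-like) one.
#' @param seed Integer seed.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(parent = strain_params("parent", 0.7, 0.1, 0.02),
                            mutant = strain_params("evolved", 0.55, 0.01, 0.02),
                            chemostat = chemostat_config(D = 0.5, S_in = 25),
                            emergence = emergence_spec(70, 0.01,
                                                       mode = "frequency"),
                            sample_generations = seq(0, 445, by = 20),
                            cv = 0.05, depth = 500, thr_share = 0.02,
                            seed = 1L) {
  assert_scalar_num(cv, "cv", 0)
  assert_scalar_num(depth, "depth", 1)
  assert_scalar_num(thr_share, "thr_share", 0)
  if (thr_share >= 1) abort("thr_share must be < 1")
  stopifnot(inherits(parent, "strain_params"),
            inherits(mutant, "strain_params"),
            inherits(chemostat, "chemostat_config"),
            inherits(emergence, "emergence_spec"))
  if (is.unsorted(sample_generations, strictly = TRUE) ||
      sample_generations[1] < 0)
    abort("sample_generations must be strictly increasing and >= 0")
  structure(list(parent = parent, mutant = mutant, chemostat = chemostat,
                 emergence = emergence,
                 sample_generations = sample_generations,
                 cv = cv, depth = depth, thr_share = thr_share,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @export
default_scenario <- function(seed = 1L) scenario_config(seed = seed)

# per-strain fermentation product yields (mol product per mol glucose),
# both redox-closed; parent is homolactic-dominant (lactate:acetate = 16),
# the evolved strain mixed-acid-shifted (ratio = 7) with pyruvate overflow
STOICH_PARENT <- c(lactate = 16 / 9, acetate = 1 / 9, ethanol = 1 / 9,
                   formate = 2 / 9, pyruvate = 0)
STOICH_MUTANT <- c(lactate = 7 * 0.8 / 4.5, acetate = 0.8 / 4.5,
                   ethanol = 1.7 / 4.5, formate = 2.5 / 4.5, pyruvate = 0.2)

#' Generate a synthetic prolonged-cultivation dataset
#'
#' Runs the deterministic two-strain wash-in model for the scenario, then
#' emulates the measurements: biomass (OD-like) with multiplicative
#' lognormal noise, steady-state metabolite concentrations from per-strain
#' fermentation stoichiometries (lactate, acetate, formate, ethanol,
#' pyruvate; mixture weighted by strain fraction, lognormal noise), and
#' pyrosequencing variant read counts (multinomial over wild-type / major /
#' minor variant at the configured depth).
#'
#' @param config A [scenario_config()].
#' @return List with data.frames `biomass` (generation, biomass),
#'   `metabolites` (generation, metabolite, conc_mM), `pyroseq` (generation,
#'   variant, reads, fraction), the noise-free `fractions`
#'   ([fraction_series()]), the deterministic `trajectory`, and `truth`
#'   (all generator parameters).
#' @export
generate_evolution_dataset <- function(config = default_scenario()) {
  stopifnot(inherits(config, "scenario_config"))
  D <- config$chemostat$D
  gens <- config$sample_generations
  t_end <- generations_to_hours(max(gens), D) + 1e-6
  sim <- simulate_washin(config$parent, config$mutant, config$chemostat,
                         config$emergence, t_end, sample_generations = gens)
  f <- sim$fractions$fraction
  traj <- sim$trajectory
  keep <- match_generations(hours_to_generations(traj$times, D), gens)
  x_tot <- rowSums(traj$x)[keep]
  S <- traj$S[keep]
  glc_consumed <- config$chemostat$S_in - S

  mets <- names(STOICH_PARENT)
  conc_true <- vapply(mets, function(m)
    glc_consumed * ((1 - f) * STOICH_PARENT[[m]] + f * STOICH_MUTANT[[m]]),
    numeric(length(gens)))

  out <- with_seed(config$seed, {
    noise <- function(n) if (config$cv > 0)
      rlnorm(n, -0.5 * log(1 + config$cv^2),
             sqrt(log(1 + config$cv^2))) else rep(1, n)
    biomass <- data.frame(generation = gens,
                          biomass = x_tot * noise(length(gens)))
    metabolites <- data.frame(
      generation = rep(gens, times = length(mets)),
      metabolite = rep(mets, each = length(gens)),
      conc_mM = as.vector(conc_true) * noise(length(gens) * length(mets)))
    reads <- t(vapply(f, function(fi)
      generate_pyroseq_counts(
        c(wildtype = 1 - fi, ile = fi * (1 - config$thr_share),
          thr = fi * config$thr_share),
        depth = config$depth),
      numeric(3)))
    list(biomass = biomass, metabolites = metabolites, reads = reads)
  })
  pyroseq <- data.frame(
    generation = rep(gens, times = 3L),
    variant = rep(c("wildtype", "ile", "thr"), each = length(gens)),
    reads = as.vector(out$reads),
    fraction = as.vector(out$reads) / config$depth)
  list(biomass = out$biomass, metabolites = out$metabolites,
       pyroseq = pyroseq, fractions = sim$fractions, trajectory = traj,
       truth = list(parent = config$parent, mutant = config$mutant,
                    chemostat = config$chemostat,
                    emergence = config$emergence,
                    stoich_parent = STOICH_PARENT,
                    stoich_mutant = STOICH_MUTANT,
                    cv = config$cv, depth = config$depth,
                    thr_share = config$thr_share, seed = config$seed))
}

#' Multinomial pyrosequencing read counts
#'
#' @param fractions Named per-variant frequencies, summing to 1 within 1e-9,
#'   all >= 0; two or more variants.
#' @param depth Total reads, >= 1.
#' @param seed Optional seed (omit to draw from the current RNG stream, as
#'   [generate_evolution_dataset()] does inside its own seeded block).
#' @return Named integer counts summing to `depth`.
#' @export
generate_pyroseq_counts <- function(fractions, depth, seed = NULL) {
  if (any(fractions < 0)) abort("negative frequency rejected")
  if (abs(sum(fractions) - 1) > 1e-9)
    abort("frequencies must sum to 1 (got %.12g)", sum(fractions))
  if (!is.numeric(depth) || depth < 1)
    abort("depth must be >= 1 (empty counts rejected)")
  draw <- function() drop(rmultinom(1L, size = as.integer(depth),
                                    prob = fractions))
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  setNames(as.numeric(counts), names(fractions))
}

#' Generate promoter sequences with planted cre sites
#'
#' Background bases are i.i.d. with the stated GC content; planted sites are
#' written exactly at the stated 0-based positions (reverse-complemented
#' when planted on the minus strand). Overlapping planted sites are
#' rejected.
#'
#' @param n Number of sequences.
#' @param length Sequence length (bp).
#' @param planted Optional data.frame with columns `seq` (index or id),
#'   `site` (A/C/G/T string), `start` (0-based), `strand` (`"+"`/`"-"`).
#' @param gc Background GC content in (0, 1), default 0.5.
#' @param seed Integer seed.
#' @return List with `sequences` (named character; convert with
#'   `Biostrings::DNAStringSet()` for FASTA output) and `truth` (the planted
#'   table with seq ids resolved).
#' @export
generate_promoters <- function(n, length, planted = NULL, gc = 0.5,
                               seed = 1L) {
  assert_scalar_num(n, "n", 1)
  assert_scalar_num(length, "length", 1)
  assert_scalar_num(gc, "gc", 0, strict = TRUE)
  if (gc >= 1) abort("gc must be in (0, 1)")
  ids <- sprintf("promoter_%03d", seq_len(n))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = ""), ""))
  names(seqs) <- ids
  truth <- data.frame(seq_id = character(), start = integer(),
                      strand = character(), site = character())
  if (!is.null(planted) && NROW(planted)) {
    if (!all(c("seq", "site", "start") %in% names(planted)))
      abort("planted needs columns seq, site, start (and optional strand)")
    strand <- if ("strand" %in% names(planted)) planted$strand
              else rep("+", nrow(planted))
    idx <- if (is.numeric(planted$seq)) as.integer(planted$seq)
           else match(as.character(planted$seq), ids)
    if (any(is.na(idx)) || any(idx < 1L | idx > n))
      abort("planted 'seq' not found")
    for (i in order(idx, planted$start)) {
      site <- check_site_string(planted$site[i])
      L <- nchar(site)
      s0 <- planted$start[i]
      if (s0 < 0 || s0 + L > length)
        abort("planted site does not fit: start %d, length %d", s0, L)
      prev <- truth[truth$seq_id == ids[idx[i]], , drop = FALSE]
      if (any(s0 < prev$start + nchar(prev$site) &
              s0 + L > prev$start))
        abort("overlapping planted sites rejected")
      written <- if (strand[i] == "-") revcomp(site) else site
      seqs[idx[i]] <- paste0(substr(seqs[idx[i]], 1, s0), written,
                             substr(seqs[idx[i]], s0 + L + 1, length))
      truth <- rbind(truth, data.frame(seq_id = ids[idx[i]], start = s0,
                                       strand = strand[i], site = site))
    }
  }
  list(sequences = seqs, truth = truth)
}

#' Generate Michaelis-Menten uptake measurements
#'
#' \eqn{v = V_{max} S / (K_m + S)} with multiplicative lognormal noise.
#'
#' @param Vmax,Km True kinetic parameters, > 0.
#' @param S_levels Concentrations, > 0 (default a log-spread of the
#'   1.2-200 uM assay range).
#' @param cv Coefficient of variation of the multiplicative noise, >= 0.
#' @param replicates Replicates per concentration, >= 1.
#' @param seed Integer seed.
#' @return List with `data` (data.frame `S`, `v`, `replicate`) and `truth`.
#' @export
generate_uptake_data <- function(Vmax, Km,
                                 S_levels = c(1.2, 2.5, 5, 10, 25, 50, 100,
                                              200),
                                 cv = 0.05, replicates = 3L, seed = 1L) {
  assert_scalar_num(Vmax, "Vmax", 0, strict = TRUE)
  assert_scalar_num(Km, "Km", 0, strict = TRUE)
  if (any(S_levels <= 0)) abort("S_levels must be positive")
  assert_scalar_num(cv, "cv", 0)
  assert_scalar_num(replicates, "replicates", 1)
  S <- rep(S_levels, times = replicates)
  v_true <- Vmax * S / (Km + S)
  v <- with_seed(seed, {
    if (cv > 0)
      v_true * rlnorm(length(S), -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))
    else v_true
  })
  list(data = data.frame(S = S, v = v,
                         replicate = rep(seq_len(replicates),
                                         each = length(S_levels))),
       truth = list(Vmax = Vmax, Km = Km, cv = cv, seed = seed))
}
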