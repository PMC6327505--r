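## Scalar physiology and genomics side-computations: chemostat specific
## fluxes, fermentation-mode metrics and ATP stoichiometry, mutation-rate
## arithmetic, Michaelis-Menten uptake kinetics, codon annotation.

#' Specific flux of a metabolite in a chemostat at steady state
#'
#' At steady state the net specific production rate of a metabolite is
#' \eqn{q = D (c_{out} - c_{in}) / X} (mmol per biomass-unit per hour).
#' Products come out positive; consumed substrates come out negative unless
#' `as_uptake = TRUE`, which flips the sign so uptake is reported positive.
#'
#' @param D Dilution rate (h^-1), >= 0.
#' @param c_out Effluent (reactor) concentration, mM.
#' @param c_in Feed concentration, mM.
#' @param X Biomass concentration (biomass-unit), > 0.
#' @param as_uptake Report consumption as positive uptake.
#' @return Specific rate q (mmol biomass-unit^-1 h^-1).
#' @examples
#' specific_flux(0.5, c_out = 0.2, c_in = 25, X = 1, as_uptake = TRUE) # 12.4
#' @export
specific_flux <- function(D, c_out, c_in, X, as_uptake = FALSE) {
  assert_scalar_num(D, "D", 0)
  if (!is.numeric(X) || any(X <= 0)) abort("zero or negative biomass rejected")
  q <- D * (c_out - c_in) / X
  if (as_uptake) -q else q
}

#' Fermentation-mode metrics from measured fluxes
#'
#' Computes the lactate:acetate flux ratio and labels the fermentation mode:
#' `"homolactic-dominant"` when the ratio is at or above `threshold`
#' (default 10, between the homolactic ~16 and the mixed-acid-shifted ~7),
#' otherwise `"mixed-acid-shifted"`. Zero acetate flux gives an infinite
#' ratio and the homolactic label.
#'
#' @param q_lactate,q_acetate Specific fluxes (>= 0).
#' @param threshold Label threshold on the ratio.
#' @return List with `ratio` and `mode`.
#' @examples
#' fermentation_metrics(16, 1) # homolactic-dominant
#' fermentation_metrics(7, 1)  # mixed-acid-shifted
#' @export
fermentation_metrics <- function(q_lactate, q_acetate, threshold = 10) {
  assert_scalar_num(q_lactate, "q_lactate", 0)
  assert_scalar_num(q_acetate, "q_acetate", 0)
  ratio <- if (q_acetate == 0) Inf else q_lactate / q_acetate
  list(ratio = ratio,
       mode = if (ratio >= threshold) "homolactic-dominant"
              else "mixed-acid-shifted")
}

#' Fermentation stoichiometry per mole of glucose
#'
#' Describes a glucose catabolic mode by its product counts (mol per mol
#' glucose). Glycolysis splits glucose into 2 pyruvate, producing 2 NADH and
#' a net 2 ATP. Pyruvate is then either reduced to lactate (consumes 1
#' NADH), excreted, or cleaved by pyruvate-formate lyase to acetyl-CoA +
#' formate; acetyl-CoA yields acetate (+1 ATP via acetate kinase) or ethanol
#' (consumes 2 NADH). Acetyl units beyond the formate count are taken to
#' come from the dehydrogenase route (CO2 + 1 NADH instead of formate).
#'
#' @param lactate,acetate,ethanol,formate,pyruvate Product counts per
#'   glucose, >= 0. `pyruvate` is excreted pyruvate (overflow).
#' @return A `fermentation_stoichiometry` with derived `nadh_balance`
#'   (produced minus consumed; 0 for a redox-closed mode), `co2` and
#'   `carbon_balance` (total product carbon incl. CO2; 6 when closed).
#' @export
fermentation_stoichiometry <- function(lactate = 0, acetate = 0, ethanol = 0,
                                       formate = 0, pyruvate = 0) {
  v <- c(lactate = lactate, acetate = acetate, ethanol = ethanol,
         formate = formate, pyruvate = pyruvate)
  if (any(!is.finite(v)) || any(v < 0)) abort("product counts must be >= 0")
  acetyl <- acetate + ethanol
  if (formate > acetyl + 1e-9)
    abort("formate (%g) cannot exceed acetyl units (%g)", formate, acetyl)
  pyr_total <- lactate + pyruvate + acetyl
  if (abs(pyr_total - 2) > 1e-9)
    abort("pyruvate accounting: lactate + excreted pyruvate + acetyl units must equal 2 per glucose (got %g)",
          pyr_total)
  co2 <- acetyl - formate               # dehydrogenase route
  nadh <- 2 + co2 - lactate - 2 * ethanol
  carbon <- 3 * lactate + 2 * acetate + 2 * ethanol + formate +
    3 * pyruvate + co2
  structure(list(lactate = lactate, acetate = acetate, ethanol = ethanol,
                 formate = formate, pyruvate_excreted = pyruvate,
                 co2 = co2, nadh_balance = nadh, carbon_balance = carbon),
            class = "fermentation_stoichiometry")
}

#' ATP yield per glucose of a fermentation mode
#'
#' Counts substrate-level phosphorylations: net 2 ATP from glycolysis plus 1
#' ATP per acetate (acetate kinase). Homolactic fermentation (2 lactate)
#' yields 2 ATP/glucose; redox-balanced mixed-acid fermentation (1 acetate,
#' 1 ethanol, 2 formate) yields 3 ATP/glucose - a 50% increase. Modes whose
#' NADH balance is not closed are rejected.
#'
#' @param stoich A [fermentation_stoichiometry()].
#' @return `atp_per_glucose` (numeric scalar).
#' @examples
#' atp_yield(fermentation_stoichiometry(lactate = 2))                    # 2
#' atp_yield(fermentation_stoichiometry(acetate = 1, ethanol = 1,
#'                                      formate = 2))                    # 3
#' @export
atp_yield <- function(stoich) {
  stopifnot(inherits(stoich, "fermentation_stoichiometry"))
  if (abs(stoich$nadh_balance) > 1e-9)
    abort("redox-imbalanced stoichiometry: NADH %s of %g per glucose",
          if (stoich$nadh_balance > 0) "surplus" else "deficit",
          abs(stoich$nadh_balance))
  2 + stoich$acetate
}

#' @rdname atp_yield
#' @param from,to Two [fermentation_stoichiometry()] modes.
#' @return `atp_increase()`: percent increase in ATP/glucose from `from`
#'   to `to`.
#' @export
atp_increase <- function(from, to) {
  100 * (atp_yield(to) / atp_yield(from) - 1)
}

#' Per-base-pair, per-generation mutation rate
#'
#' `rate = snp_count / (genome_length * generations)`. With 1-6 SNPs on a
#' 2.5 Mb genome over 309 doublings this reproduces the canonical
#' 1.3-7.8e-9 range.
#'
#' @param snp_count Number of SNPs accumulated (>= 0, vectorised).
#' @param genome_length Genome size in bp, > 0. Default 2.5e6.
#' @param generations Number of doublings, > 0.
#' @return Mutation rate per bp per generation.
#' @export
mutation_rate <- function(snp_count, genome_length = 2.5e6, generations) {
  if (any(snp_count < 0)) abort("snp_count must be >= 0")
  if (!is.numeric(genome_length) || any(genome_length <= 0))
    abort("genome_length must be > 0")
  if (!is.numeric(generations) || any(generations <= 0))
    abort("generations must be > 0")
  snp_count / (genome_length * generations)
}

#' Fit Michaelis-Menten uptake kinetics
#'
#' Nonlinear least squares of \eqn{v = V_{max} S / (K_m + S)} via
#' [stats::nls()] (port algorithm, positivity bounds), with deterministic
#' initialisation `Vmax0 = max(v)`, `Km0 = median(S)`. Wald confidence
#' intervals from the asymptotic covariance.
#'
#' Radiotracer uptake measurements carry roughly proportional error, so the
#' default `error_model = "proportional"` minimises residuals of `log(v)`
#' (equivalent to a multiplicative lognormal error model and exact at zero
#' noise); `"absolute"` is classical unweighted least squares on `v`.
#'
#' @param S Substrate concentrations (e.g. uM), > 0, at least 3 distinct.
#' @param v Measured rates (same length as `S`).
#' @param level Confidence level (default 0.95).
#' @param error_model `"proportional"` (default) or `"absolute"`.
#' @return List with `Vmax`, `Km`, `se` (named), `ci` (2x2 matrix), `fitted`
#'   function, and the `nls` object.
#' @export
fit_uptake_kinetics <- function(S, v, level = 0.95,
                                error_model = c("proportional", "absolute")) {
  error_model <- match.arg(error_model)
  if (length(S) != length(v)) abort("S and v lengths differ")
  if (any(!is.finite(S)) || any(S <= 0))
    abort("non-positive concentrations rejected")
  if (length(unique(S)) < 3L)
    abort("need at least 3 distinct concentrations (got %d)",
          length(unique(S)))
  start <- list(Vmax = max(v), Km = unname(median(S)))
  dat <- data.frame(S = S, v = v)
  form <- if (error_model == "proportional") {
    if (any(v <= 0)) abort("proportional error model needs positive rates")
    log(v) ~ log(Vmax * S / (Km + S))
  } else v ~ Vmax * S / (Km + S)
  fit <- tryCatch(
    nls(form, data = dat, start = start,
        algorithm = "port", lower = c(Vmax = 1e-12, Km = 1e-12),
        control = list(warnOnly = FALSE)),
    error = function(e) abort("uptake fit failed: %s", conditionMessage(e)))
  est <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(low = est - z * se, high = est + z * se)
  list(Vmax = unname(est["Vmax"]), Km = unname(est["Km"]),
       se = se, ci = ci,
       fitted = function(s) unname(est["Vmax"]) * s / (unname(est["Km"]) + s),
       fit = fit)
}


codon_to_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) abort("invalid codon '%s'", codon)
  aa
}

#' Annotate a coding SNP from its reference and alternate codons
#'
#' Translates both codons with the standard genetic code and flags the
#' change as synonymous when the amino acids agree.
#'
#' @param ref_codon,alt_codon Length-3 strings over A/C/G/T.
#' @param position Optional 1-based genome coordinate.
#' @param locus Optional locus label.
#' @return A `snp_record`: list with `position`, `locus`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `synonymous`.
#' @examples
#' annotate_snp("ATG", "ATA") # Met -> Ile, non-synonymous
#' @export
annotate_snp <- function(ref_codon, alt_codon, position = NA_integer_,
                         locus = NA_character_) {
  for (cd in c(ref_codon, alt_codon)) {
    if (!is.character(cd) || length(cd) != 1L || nchar(cd) != 3L)
      abort("codons must be length-3 strings (got '%s')", cd)
    if (grepl("[^ACGTacgt]", cd))
      abort("codon '%s' contains non-ACGT characters", cd)
  }
  ref_aa <- codon_to_aa(ref_codon)
  alt_aa <- codon_to_aa(alt_codon)
  structure(list(position = position, locus = locus,
                 ref_codon = toupper(ref_codon),
                 alt_codon = toupper(alt_codon),
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 synonymous = identical(ref_aa, alt_aa)),
            class = "snp_record")
}

#' @export
print.snp_record <- function(x, ...) {
  cat(sprintf("<snp_record> %s>%s: %s>%s (%s)%s\n",
              x$ref_codon, x$alt_codon, x$ref_aa, x$alt_aa,
              if (x$synonymous) "synonymous" else "non-synonymous",
              if (!is.na(x$locus)) paste0(" @", x$locus) else ""))
  invisible(x)
}
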