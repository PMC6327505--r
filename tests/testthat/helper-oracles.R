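# Shared fixtures and independent oracles. Everything here is deliberately
# written without calling the package's own numerical paths: the RK4
# integrator, IUPAC sets and reverse complement are independent routes used
# to cross-check the implementation.

default_parent <- function() strain_params("parent", 0.7, 0.1, 0.02)
default_mutant <- function() strain_params("evolved", 0.55, 0.01, 0.02)
default_config <- function(D = 0.5) chemostat_config(D = D, S_in = 25)

truth_params <- function() {
  list(mu_parent = 0.7, km_parent = 0.1, yield_parent = 0.02,
       mu_mutant = 0.55, km_mutant = 0.01, yield_mutant = 0.02,
       amount = 0.01, t_emerge = 70)
}

# independent fixed-step classical RK4 for the chemostat ODEs
rk4_oracle <- function(strains, D, S_in, y0, t_end, dt = 0.001) {
  rhs <- function(y) {
    S <- y[1]
    mu <- vapply(strains, function(st) st$mu_max * S / (st$K_M + S), 0)
    x <- y[-1]
    c(D * (S_in - S) -
        sum(mu * x / vapply(strains, `[[`, 0, "yield")),
      (mu - D) * x)
  }
  y <- y0
  n <- ceiling(t_end / dt)
  h <- t_end / n
  for (i in seq_len(n)) {
    k1 <- rhs(y); k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2); k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y[y < 0] <- 0
  }
  y
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

brute_mismatch <- function(site, pattern = "TGNNANCGNTTNCA") {
  s <- strsplit(site, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  stopifnot(length(s) == length(p))
  sum(vapply(seq_along(s), function(i) !(s[i] %in% IUPAC_SETS[[p[i]]]), TRUE))
}

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
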