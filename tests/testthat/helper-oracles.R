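# Independent oracles, kept deliberately separate from the package internals.

# Atomic monoisotopic masses (CODATA/IUPAC).
ATOM <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
          S = 31.97207117, D = 2.01410178, C13 = 13.00335484,
          N15 = 15.00010897)

# Residue elemental compositions (peptide-bond residues).
RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

formula_mass <- function(formula) sum(ATOM[names(formula)] * formula)

# Modification shifts from elemental arithmetic.
oracle_shift <- function(state) {
  ch2 <- formula_mass(c(C = 1, H = 2))
  acetyl <- formula_mass(c(C = 2, H = 2, O = 1))
  d3acetyl <- acetyl + 3 * (ATOM[["D"]] - ATOM[["H"]])
  switch(state,
         unmod = 0, me1 = ch2, me2 = 2 * ch2, me3 = 3 * ch2, ac = acetyl,
         d3ac = d3acetyl, d3ac_me1 = d3acetyl + ch2,
         stop("unknown state"))
}

# Brute-force peptidoform mass: atom-level sums, no shared code with the
# package's residue-mass table.
oracle_mass <- function(sequence, states = character(0)) {
  res <- strsplit(sequence, "")[[1]]
  water <- formula_mass(c(H = 2, O = 1))
  base <- sum(vapply(res, function(r) formula_mass(RESIDUE_FORMULA[[r]]), 0))
  base + water + sum(vapply(unname(states), oracle_shift, 0))
}

oracle_arg10 <- function() {
  6 * (ATOM[["C13"]] - ATOM[["C"]]) + 4 * (ATOM[["N15"]] - ATOM[["N"]])
}

# Naive split-after-R digestion oracle (no missed cleavages).
oracle_digest <- function(sequence) {
  frags <- strsplit(gsub("R", "R|", sequence), "|", fixed = TRUE)[[1]]
  frags[nzchar(frags)]
}

# Two-Gaussian chromatogram fixture on a regular grid.
two_gaussian_trace <- function(area1, area2, apex1 = 10, apex2 = 12,
                               sd = 0.3, step = 0.02) {
  rt <- seq(apex1 - 5 * sd, apex2 + 5 * sd, by = step)
  data.frame(rt = rt,
             intensity = area1 * dnorm(rt, apex1, sd) +
               area2 * dnorm(rt, apex2, sd))
}

# Noise-free cohort configuration used by several round-trip tests.
noiseless_config <- function(n = c(normal = 1, tumor = 1), ...) {
  cohort_config(n_per_group = n, noise_sd = 0, sample_scale_sd = 0,
                missing_rate = 0,
                ki67 = list(mean = c(normal = 15, tumor = 45), sd = 8,
                            link_mark = NULL, link_r = 0, bio_sd = 0), ...)
}
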