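# Substrate model: derivatized histone H3, Arg-C-like digestion, combinatorial
# peptidoform enumeration and exact mass / m/z computation for the light and
# Arg-10 heavy (super-SILAC) channels.

# Monoisotopic residue masses (Da), standard 20 amino acids.
.AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047678, C = 103.009185, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313
)

.MASS_WATER <- 18.0105646
#' Physical constants used for ion m/z computation
#'
#' Proton mass and the mass shift of the Arg-10 label
#' (\eqn{{}^{13}C_6{}^{15}N_4}-arginine) used in the super-SILAC spike-in.
#' Stated once; every heavy-channel m/z in the package derives from these.
#'
#' @format Named numeric vector with elements `proton` (1.0072765 Da) and
#'   `arg10` (10.00827 Da per arginine).
#' @export
ion_constants <- c(proton = 1.0072765, arg10 = 10.00827)

# Lysine modification states.  After chemical derivatization with D6-acetic
# anhydride, an endogenously unmodified lysine carries d3-acetyl ("d3ac") and a
# monomethylated lysine carries d3-acetyl + me1 ("d3ac_me1"); me2/me3/ac block
# the reagent and stay as-is.
.MOD_STATES <- c("unmod", "me1", "me2", "me3", "ac", "d3ac", "d3ac_me1")

# Full-precision shifts from atomic monoisotopic masses:
# CH2 = 14.0156501; acetyl C2H2O = 42.0105646; d3-acetyl replaces 3 H by D
# (+3 x 1.00627675).
.MOD_SHIFT_FULL <- c(
  unmod    = 0,
  me1      = 14.0156501,
  me2      = 28.0313001,
  me3      = 42.0469502,
  ac       = 42.0105646,
  d3ac     = 45.0293949,
  d3ac_me1 = 59.0450450
)

# The values as configured in the database-search setup (printed precision);
# me3/ac are truncations of the exact values, kept verbatim as configured
# echoes, never mixed with the full-precision table.
.MOD_SHIFT_CONFIGURED <- c(
  unmod    = 0,
  me1      = 14.016,
  me2      = 28.031,
  me3      = 42.046,
  ac       = 42.010,
  d3ac     = 45.0294,
  d3ac_me1 = 45.0294 + 14.016
)

#' Lysine modification mass shifts
#'
#' Monoisotopic mass shift for a lysine modification state, either at full
#' double precision (derived from atomic masses) or as configured in the
#' variable-modification table of the database search. The composite
#' `d3ac_me1` state (monomethyl lysine after d3-acetyl derivatization) equals
#' the sum of the `d3ac` and `me1` shifts in both modes.
#'
#' @param state Character vector of states among
#'   `"unmod"`, `"me1"`, `"me2"`, `"me3"`, `"ac"`, `"d3ac"`, `"d3ac_me1"`.
#' @param precision `"full"` (default) or `"configured"`.
#' @return Numeric vector of shifts in Da.
#' @examples
#' mod_shift("d3ac", "configured")   # 45.0294
#' mod_shift("d3ac_me1", "configured")  # 59.0454
#' @export
mod_shift <- function(state, precision = c("full", "configured")) {
  precision <- match.arg(precision)
  bad <- setdiff(state, .MOD_STATES)
  if (length(bad) > 0) {
    stop("unknown modification state(s): ", paste(bad, collapse = ", "))
  }
  tab <- if (precision == "full") .MOD_SHIFT_FULL else .MOD_SHIFT_CONFIGURED
  unname(tab[state])
}

#' Mature histone H3 reference sequence
#'
#' Canonical mature human H3.1 (initiator methionine removed, so A = residue 1,
#' matching the "9-17" span nomenclature). The mouse sequence is identical over
#' the peptide families covered here, so this single reference serves both.
#'
#' @return Single character string of 135 residues.
#' @export
h3_reference <- function() {
  fa <- system.file("extdata", "h3_reference.fasta", package = "histonePTM",
                    mustWork = TRUE)
  unname(read_reference_fasta(fa)[1])
}

#' Read a protein reference from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

.check_residues <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(.AA_MONO))
  if (length(bad) > 0) {
    stop("non-standard residue '", res[bad[1]], "' at position ", bad[1])
  }
  res
}

#' In-silico Arg-C-like digestion of a derivatized protein
#'
#' Chemical d3-acetylation of lysines before trypsin digestion blocks cleavage
#' after K, so the digest cleaves strictly C-terminal of arginine
#' ("Arg-C-like"). With `missed_cleavages = m`, all concatenations of up to
#' `m + 1` adjacent fragments are returned.
#'
#' @param sequence Protein sequence (standard residues only).
#' @param missed_cleavages Non-negative integer, maximum missed cleavages.
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   `sequence`, `n_missed`.
#' @examples
#' derivatize_and_digest("ARTKQTARKSTGGKAPRKQLATKAAR", 0)
#' @export
derivatize_and_digest <- function(sequence, missed_cleavages = 0) {
  stopifnot(length(sequence) == 1, missed_cleavages >= 0)
  res <- .check_residues(sequence)
  n <- length(res)
  # fragment boundaries: cut after every R
  cut_after <- which(res == "R")
  ends <- unique(c(cut_after, n))
  starts <- c(1, utils::head(ends, -1) + 1)
  starts <- starts[starts <= n]
  ends <- ends[seq_along(starts)]
  nfrag <- length(starts)
  out <- list()
  for (m in 0:missed_cleavages) {
    for (i in seq_len(nfrag - m)) {
      s <- starts[i]; e <- ends[i + m]
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e,
        sequence = paste(res[s:e], collapse = ""),
        n_missed = m, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Render a per-lysine state assignment as the field's peptide nomenclature:
# derivatized-unmodified lysines (d3ac) are silent, d3ac_me1 reads as me1,
# an all-unmodified peptide is "unmod".
.form_id <- function(states) {
  pos <- as.integer(names(states))
  shown <- character(0)
  for (i in seq_along(states)) {
    st <- states[i]
    if (st %in% c("d3ac", "unmod")) next
    lab <- if (st == "d3ac_me1") "me1" else st
    shown <- c(shown, paste0("K", pos[i], lab))
  }
  if (length(shown) == 0) "unmod" else paste(shown, collapse = "")
}

#' Enumerate combinatorial peptidoforms of one peptide span
#'
#' Takes the Cartesian product of allowed modification states over all lysines
#' of the span. Endogenously unmodified lysines are represented by their
#' derivatized state `d3ac`, and monomethylated ones by `d3ac_me1`.
#'
#' @param sequence Peptide sequence.
#' @param start 1-based position of the first residue on the reference.
#' @param allowed_states Character vector of states applied to every lysine, or
#'   a named list keyed by absolute residue position for per-site control.
#' @param family_id Identifier of the unmodified span; defaults to
#'   `"start-end"`.
#' @return data.frame with one row per peptidoform: `family_id`, `start`,
#'   `end`, `sequence`, `form_id`, `states` (e.g. `"9=me3;14=ac"`), `mass`
#'   (light monoisotopic, Da), `n_arg`. Deterministic order: the state of the
#'   first lysine varies slowest, in the given state order.
#' @export
enumerate_peptidoforms <- function(sequence, start,
                                   allowed_states = c("d3ac", "d3ac_me1",
                                                      "me2", "me3", "ac"),
                                   family_id = NULL) {
  res <- .check_residues(sequence)
  end <- start + length(res) - 1L
  if (is.null(family_id)) family_id <- paste0(start, "-", end)
  kpos <- start - 1L + which(res == "K")
  if (is.list(allowed_states)) {
    bad <- setdiff(as.integer(names(allowed_states)), kpos)
    if (length(bad) > 0) {
      stop("state assigned to non-lysine position(s): ",
           paste(bad, collapse = ", "))
    }
    state_sets <- lapply(kpos, function(p) {
      s <- allowed_states[[as.character(p)]]
      if (is.null(s)) "d3ac" else s
    })
  } else {
    state_sets <- rep(list(allowed_states), length(kpos))
  }
  for (s in unlist(state_sets)) mod_shift(s)  # validate states
  if (length(kpos) == 0) {
    grid <- data.frame(row.names = 1)
  } else {
    # first position varies slowest -> reverse, expand, reverse back
    grid <- expand.grid(rev(state_sets), stringsAsFactors = FALSE)
    grid <- grid[, rev(seq_along(state_sets)), drop = FALSE]
    names(grid) <- as.character(kpos)
  }
  n_arg <- sum(res == "R")
  base_mass <- sum(.AA_MONO[res]) + .MASS_WATER
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- stats::setNames(as.character(unlist(grid[i, , drop = FALSE])),
                          names(grid))
    data.frame(
      family_id = family_id, start = start, end = end, sequence = sequence,
      form_id = .form_id(st),
      states = if (length(st)) paste(paste0(names(st), "=", st),
                                     collapse = ";") else "",
      mass = base_mass + sum(mod_shift(st)),
      n_arg = n_arg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.parse_states <- function(states) {
  if (is.na(states) || states == "") return(stats::setNames(character(0), NULL))
  parts <- strsplit(states, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Monoisotopic mass of a peptidoform
#'
#' Residue-mass sum plus water plus full-precision modification shifts.
#'
#' @param sequence Peptide sequence.
#' @param states Named character vector of lysine states (names are absolute
#'   residue positions), or a `"9=me3;14=ac"` style string.
#' @return Mass in Da (light channel; the Arg-10 label is added at the ion
#'   level, see [ion_mz()]).
#' @examples
#' peptidoform_mass("KSTGGKAPR", c("9" = "d3ac", "14" = "d3ac"))  # 990.5729
#' @export
peptidoform_mass <- function(sequence, states = character(0)) {
  res <- .check_residues(sequence)
  if (is.character(states) && length(states) == 1 && is.null(names(states)) &&
      (grepl("=", states) || states == "")) {
    states <- .parse_states(states)
  }
  sum(.AA_MONO[res]) + .MASS_WATER + sum(mod_shift(unname(states)))
}

#' m/z of a peptidoform ion
#'
#' `(M + z * proton) / z`; the heavy (super-SILAC) channel adds the Arg-10
#' shift of 10.00827 Da per arginine to M before division.
#'
#' @param mass Monoisotopic light mass in Da.
#' @param charge Ion charge, 2 or 3.
#' @param channel `"light"` or `"heavy"`.
#' @param n_arg Number of arginines in the peptide (needed for `"heavy"`).
#' @return m/z in Da per unit charge.
#' @export
ion_mz <- function(mass, charge, channel = c("light", "heavy"), n_arg = 0) {
  channel <- match.arg(channel)
  if (!all(charge %in% c(2, 3))) stop("charge must be 2 or 3")
  m <- mass + if (channel == "heavy") n_arg * ion_constants[["arg10"]] else 0
  (m + charge * ion_constants[["proton"]]) / charge
}

# Default per-family lysine state sets: the combinatorial forms the assay
# routinely quantifies on histone H3 (K14/K23/K37 methylation and K36
# acetylation are not enumerated by default).
.default_h3_states <- function() {
  all5 <- c("d3ac", "d3ac_me1", "me2", "me3", "ac")
  list(
    "3-8"   = list("4" = all5),
    "9-17"  = list("9" = all5, "14" = c("d3ac", "ac")),
    "18-26" = list("18" = c("d3ac", "ac", "d3ac_me1"),
                   "23" = c("d3ac", "ac")),
    "27-40" = list("27" = all5,
                   "36" = c("d3ac", "d3ac_me1", "me2", "me3"),
                   "37" = "d3ac"),
    "73-83" = list("79" = all5)
  )
}

#' Build the histone H3 peptidoform library
#'
#' Digests the reference in-silico (Arg-C-like), enumerates the combinatorial
#' peptidoforms of the requested peptide families with the default (or
#' user-supplied) per-lysine state sets, and attaches light/heavy m/z values
#' for the 2+ and 3+ precursors.
#'
#' @param reference Reference protein sequence; defaults to mature H3.
#' @param families Character vector of family ids among `"3-8"`, `"9-17"`,
#'   `"18-26"`, `"27-40"`, `"73-83"` (spans on the mature H3 numbering).
#' @param states Named list (by family id) of per-position state lists; see
#'   [enumerate_peptidoforms()]. Defaults to the standard assay panel.
#' @return data.frame: one row per peptidoform with columns `family_id`,
#'   `start`, `end`, `sequence`, `form_id`, `states`, `mass`, `n_arg`,
#'   `mz_light_z2`, `mz_heavy_z2`, `mz_light_z3`, `mz_heavy_z3`.
#' @export
build_h3_library <- function(reference = h3_reference(),
                             families = names(.default_h3_states()),
                             states = .default_h3_states()) {
  digest <- derivatize_and_digest(reference, missed_cleavages = 0)
  digest$family_id <- paste0(digest$start, "-", digest$end)
  missing_fam <- setdiff(families, digest$family_id)
  if (length(missing_fam) > 0) {
    stop("families not produced by digestion: ",
         paste(missing_fam, collapse = ", "))
  }
  libs <- lapply(families, function(f) {
    row <- digest[digest$family_id == f, ]
    st <- states[[f]]
    if (is.null(st)) st <- c("d3ac", "d3ac_me1", "me2", "me3", "ac")
    enumerate_peptidoforms(row$sequence, row$start, allowed_states = st,
                           family_id = f)
  })
  lib <- do.call(rbind, libs)
  lib$mz_light_z2 <- ion_mz(lib$mass, 2, "light")
  lib$mz_heavy_z2 <- mapply(ion_mz, lib$mass, n_arg = lib$n_arg,
                            MoreArgs = list(charge = 2, channel = "heavy"))
  lib$mz_light_z3 <- ion_mz(lib$mass, 3, "light")
  lib$mz_heavy_z3 <- mapply(ion_mz, lib$mass, n_arg = lib$n_arg,
                            MoreArgs = list(charge = 3, channel = "heavy"))
  lib
}

#' Export a peptidoform library as TSV
#'
#' @param library data.frame from [build_h3_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_library_tsv <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
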