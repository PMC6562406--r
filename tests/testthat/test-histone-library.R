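# Substrate model: digestion, peptidoform enumeration, masses and m/z.

test_that("Arg-C-like digestion cleaves after R only, with missed cleavages", {
  d0 <- derivatize_and_digest("ARTKQTARKSTGGKAPRKQLATKAAR", 0)
  expect_equal(d0$sequence, c("AR", "TKQTAR", "KSTGGKAPR", "KQLATKAAR"))
  expect_equal(d0$start, c(1, 3, 9, 18))
  expect_equal(d0$end, c(2, 8, 17, 26))

  d1 <- derivatize_and_digest("ARTKQTARKSTGGKAPRKQLATKAAR", 1)
  extra <- d1[d1$n_missed == 1, ]
  expect_equal(paste(extra$start, extra$end),
               c("1 8", "3 17", "9 26"))

  plain <- derivatize_and_digest("AAAA", 0)
  expect_equal(nrow(plain), 1)
  expect_equal(c(plain$start, plain$end), c(1, 4))

  expect_error(derivatize_and_digest("ARTZK", 0), "position 4")
})

test_that("digestion equals naive split-after-R on random sequences", {
  set.seed(11)
  aas <- c("A", "G", "S", "T", "K", "R", "P", "L", "V", "E", "Q", "F")
  for (i in 1:1000) {
    s <- paste(sample(aas, sample(5:40, 1), replace = TRUE), collapse = "")
    got <- derivatize_and_digest(s, 0)$sequence
    expect_identical(got, oracle_digest(s))
  }
})

test_that("peptidoform enumeration is the Cartesian product over lysines", {
  all5 <- c("d3ac", "d3ac_me1", "me2", "me3", "ac")
  f917 <- enumerate_peptidoforms("KSTGGKAPR", 9, all5)
  expect_equal(nrow(f917), 25)
  expect_false(anyDuplicated(f917$states) > 0)

  no_k <- enumerate_peptidoforms("TQTAR", 4)
  expect_equal(nrow(no_k), 1)
  expect_equal(no_k$form_id, "unmod")

  f38 <- enumerate_peptidoforms("TKQTAR", 3, all5)
  expect_equal(nrow(f38), 5)
  expect_equal(f38$form_id[1:2], c("unmod", "K4me1"))

  # random spans: count is the product of per-lysine state-set sizes
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(c("K", "A", "G", "S", "T"), sample(4:9, 1),
                      replace = TRUE), collapse = "")
    k <- sum(strsplit(s, "")[[1]] == "K")
    nst <- sample(2:4, 1)
    got <- enumerate_peptidoforms(s, 1, all5[seq_len(nst)])
    expect_equal(nrow(got), nst^k)
  }

  expect_error(
    enumerate_peptidoforms("KSTGGKAPR", 9,
                           allowed_states = list("10" = "ac")),
    "non-lysine")
})

test_that("modification shifts match printed search values and atomic masses", {
  expect_equal(mod_shift("d3ac", "configured"), 45.0294)
  expect_equal(mod_shift("me1", "configured"), 14.016)
  expect_equal(mod_shift("me2", "configured"), 28.031)
  expect_equal(mod_shift("me3", "configured"), 42.046)
  expect_equal(mod_shift("ac", "configured"), 42.010)
  expect_equal(mod_shift("d3ac_me1", "configured"),
               mod_shift("d3ac", "configured") +
                 mod_shift("me1", "configured"))
  for (st in c("me1", "me2", "me3", "ac", "d3ac", "d3ac_me1")) {
    expect_equal(mod_shift(st, "full"), oracle_shift(st), tolerance = 1e-6)
  }
  expect_equal(mod_shift("me1", "full"), 14.01565, tolerance = 1e-5)
  expect_error(mod_shift("phospho"), "unknown modification state")
})

test_that("peptidoform masses agree with the elemental brute-force oracle", {
  expect_equal(peptidoform_mass("KSTGGKAPR",
                                c("9" = "d3ac", "14" = "d3ac")),
               990.5729, tolerance = 1e-4)
  expect_equal(peptidoform_mass("KSTGGKAPR"), 900.5141, tolerance = 1e-4)

  all5 <- c("d3ac", "d3ac_me1", "me2", "me3", "ac")
  forms <- enumerate_peptidoforms("KSTGGKAPR", 9, all5)
  expect_equal(nrow(forms), 25)
  for (i in seq_len(nrow(forms))) {
    st <- strsplit(forms$states[i], ";")[[1]]
    kv <- do.call(rbind, strsplit(st, "="))
    states <- setNames(kv[, 2], kv[, 1])
    expect_equal(forms$mass[i], oracle_mass("KSTGGKAPR", states),
                 tolerance = 1e-4)
  }
  # mass additivity: pairwise differences equal state-shift differences
  shift_sum <- vapply(forms$states, function(s) {
    kv <- do.call(rbind, strsplit(strsplit(s, ";")[[1]], "="))
    sum(mod_shift(kv[, 2]))
  }, 0)
  diffs <- outer(forms$mass, forms$mass, "-")
  expect_equal(diffs, outer(shift_sum, shift_sum, "-"),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("ion m/z follows (M + z p)/z with the Arg-10 heavy offset", {
  m <- peptidoform_mass("KSTGGKAPR", c("9" = "d3ac", "14" = "d3ac"))
  expect_equal(ion_mz(m, 2, "light"), 496.2937, tolerance = 1e-4)
  expect_equal(ion_mz(m, 2, "heavy", n_arg = 1) - ion_mz(m, 2, "light"),
               5.0041, tolerance = 1e-4)
  # algebraic identity between charge states
  expect_equal(ion_mz(m, 2, "light") * 2 - ion_mz(m, 3, "light") * 3,
               -unname(ion_constants["proton"]), tolerance = 1e-4)
  expect_error(ion_mz(m, 4), "charge")
})

test_that("library ions carry the exact per-arginine heavy mass delta", {
  lib <- build_h3_library()
  expect_equal(sort(unique(lib$family_id)),
               c("18-26", "27-40", "3-8", "73-83", "9-17"))
  for (z in c(2, 3)) {
    delta <- (lib[[paste0("mz_heavy_z", z)]] -
                lib[[paste0("mz_light_z", z)]]) * z
    expect_equal(delta, lib$n_arg * 10.00827, tolerance = 1e-4)
    expect_equal(delta, lib$n_arg * oracle_arg10(), tolerance = 1e-3)
  }
})

test_that("reference FASTA round-trips and yields the documented spans", {
  ref <- h3_reference()
  expect_equal(nchar(ref), 135)
  dig <- derivatize_and_digest(ref, 0)
  spans <- paste0(dig$start, "-", dig$end)
  expect_true(all(c("3-8", "9-17", "18-26", "27-40", "73-83") %in% spans))
  expect_equal(dig$sequence[spans == "9-17"], "KSTGGKAPR")

  lib <- build_h3_library()
  tsv <- tempfile(fileext = ".tsv")
  export_library_tsv(lib, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(lib))
  expect_equal(back$mass, lib$mass, tolerance = 1e-9)
})
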