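nn <- nn_table()
cond <- thermo_conditions()

test_that("the parameter table is complete and internally consistent", {
  expect_equal(nrow(nn$steps), 16L)
  dev <- abs(nn$steps$dH_kcal - 310.15 * nn$steps$dS_cal / 1000 -
               nn$steps$dG37_kcal)
  expect_true(all(dev <= 0.1))
  expect_equal(unname(nn$init["dG37"]), 3.1)
})

test_that("pair_probe aligns full-length and 3'-anchored probes", {
  recs <- panel_records()
  d <- pair_probe(recs[["mmu-miR-322"]], panel_probe("mmu-miR-322", "affymetrix"))
  expect_equal(length(d$steps), 21L)
  expect_equal(d$window, recs[["mmu-miR-322"]]$seq)

  # 13-mer probe covers the miRNA 3' end: 12 steps
  d2 <- pair_probe(recs[["mmu-miR-433"]], panel_probe("mmu-miR-433", "agilent"),
                   with_tail = FALSE)
  expect_equal(length(d2$steps), 12L)
  expect_equal(d2$offset, 10L)

  # internal mismatch is rejected with its position
  bad <- probe_record("TCCAAAACATGAATTGCTGCTG", name = "bad")
  bad$base$seq <- sub("GAAT", "GTAT", bad$base$seq)
  # probe position 12 maps to duplex position 22 - 12 + 1 = 11
  expect_error(pair_probe(recs[["mmu-miR-322"]], bad), "position 11")
})

test_that("a two-step duplex is the table entry plus initiation", {
  # RNA 'AC' / DNA probe 'GT': single AC step
  r <- sequence_record("r2", "AC", "RNA")
  d <- pair_probe(r, probe_record("GT", name = "p2"))
  expect_equal(length(d$steps), 1L)
  expect_equal(hybrid_delta_g(d, nn),
               nn$steps["AC", "dG37_kcal"] + nn$init[["dG37"]])
  expect_equal(hybrid_delta_g(d, nn), -2.1 + 3.1)
})

test_that("free energy is additive over terminal steps", {
  recs <- panel_records()
  for (m in c("mmu-miR-322", "mmu-miR-127", "mmu-miR-96")) {
    rna <- recs[[m]]
    full <- reverse_complement(rna, "DNA")$seq
    # drop the probe's last base = drop the RNA window's first step
    shorter <- substr(full, 1, nchar(full) - 1)
    d_full <- pair_probe(rna, probe_record(full, name = "f"))
    d_short <- pair_probe(rna, probe_record(shorter, name = "s"))
    first_step <- d_full$steps[1]
    expect_equal(hybrid_delta_g(d_full, nn) - hybrid_delta_g(d_short, nn),
                 nn$steps[first_step, "dG37_kcal"])
  }
})

test_that("panel free energies reproduce the reference values exactly", {
  exp <- panel_expected()
  recs <- panel_records()
  for (i in seq_len(nrow(exp))) {
    m <- exp$mirna[i]
    affy <- pair_probe(recs[[m]], panel_probe(m, "affymetrix"))
    expect_within(hybrid_delta_g(affy, nn), exp$affy_dg[i], 0.05,
                  label = paste(m, "full-length dG"))
    vars <- probe_variants(recs[[m]], panel_probe(m, "agilent"), nn, cond)
    if (!is.null(vars$extended))
      expect_within(vars$extended$dG37, exp$agl_ext_dg[i], 0.05,
                    label = paste(m, "tailed dG"))
    expect_within(vars$core$dG37, exp$agl_core_dg[i], 0.05,
                  label = paste(m, "core dG"))
  }
})

test_that("panel melting temperatures match under shared conditions", {
  exp <- panel_expected()
  exp <- exp[exp$tm_consistent, ]
  recs <- panel_records()
  for (i in seq_len(nrow(exp))) {
    m <- exp$mirna[i]
    affy <- pair_probe(recs[[m]], panel_probe(m, "affymetrix"))
    expect_within(hybrid_tm(affy, nn, cond), exp$affy_tm[i], 0.5,
                  label = paste(m, "full-length Tm"))
    vars <- probe_variants(recs[[m]], panel_probe(m, "agilent"), nn, cond)
    if (!is.null(vars$extended))
      expect_within(vars$extended$tm, exp$agl_ext_tm[i], 0.5,
                    label = paste(m, "tailed Tm"))
    expect_within(vars$core$tm, exp$agl_core_tm[i], 0.5,
                  label = paste(m, "core Tm"))
  }
})

test_that("Tm falls linearly in formamide with the condition slope", {
  recs <- panel_records()
  for (m in names(recs)[c(1, 5, 11)]) {
    d <- pair_probe(recs[[m]], panel_probe(m, "affymetrix"))
    tm0 <- hybrid_tm(d, nn, thermo_conditions(formamide_pct = 0))
    tm35 <- hybrid_tm(d, nn, thermo_conditions(formamide_pct = 35))
    expect_equal(tm0 - tm35, 0.63 * 35)
    tm10 <- hybrid_tm(d, nn, thermo_conditions(formamide_pct = 10))
    expect_equal(tm0 - tm10, 6.3)
  }
})

test_that("salt term vanishes at 1 M sodium and follows 16.6 log10", {
  d <- pair_probe(panel_records()[["mmu-miR-322"]],
                  panel_probe("mmu-miR-322", "affymetrix"))
  tm1 <- hybrid_tm(d, nn, thermo_conditions(na_molar = 1))
  tm01 <- hybrid_tm(d, nn, thermo_conditions(na_molar = 0.1))
  expect_equal(tm1 - tm01, 16.6)
})

test_that("probe_variants returns extended-then-core for tailed probes", {
  recs <- panel_records()
  vars <- probe_variants(recs[["mmu-miR-15a"]], panel_probe("mmu-miR-15a", "agilent"))
  expect_named(vars, c("extended", "core"))
  expect_equal(vars$extended$paired_nt, 22L)
  expect_equal(vars$core$paired_nt, 21L)
  single <- probe_variants(recs[["mmu-miR-322"]], panel_probe("mmu-miR-322", "agilent"))
  expect_named(single, "core")
  # a tail that mismatches the miRNA is an error
  bad <- probe_record("CACAAACCATTATGTGCTGCT", optional_tail = "G", name = "bad")
  expect_error(probe_variants(recs[["mmu-miR-15a"]], bad), "mismatch")
})
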