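shift_row <- function(peptide, i, code, nucleus, temp, ppm)
  data.frame(peptide = peptide, residue_index = i, residue_code = code,
             nucleus = nucleus, temperature_K = temp, shift_ppm = ppm)

# pentapeptide shift table at 298 K built as coil + known offsets
synthetic_shifts <- function(offsets = c(0.10, 0.15, 0.20, 0.15, 0.10),
                             codes = c("ALA", "VAL", "TFS", "VAL", "LEU")) {
  coil <- coil_reference()
  ref <- vapply(codes, function(c) {
    v <- coil$table$shift_ppm[coil$table$residue_code == c &
                                coil$table$nucleus == "HA"]
    if (length(v)) v else 4.5   # placeholder for reference-less residues
  }, numeric(1))
  do.call(rbind, lapply(1:5, function(i)
    shift_row("pep", i, codes[i], "HA", 298, ref[i] + offsets[i])))
}

test_that("CSD equals observed minus coil and honors exclusion rules", {
  csd <- compute_csd(synthetic_shifts())
  expect_equal(csd$excluded, c("terminal", "", "no-reference", "", "terminal"))
  expect_equal(csd$csd_ppm[c(2, 4)], c(0.15, 0.15), tolerance = 1e-12)
  expect_true(all(is.na(csd$csd_ppm[c(1, 3, 5)])))
  # zero offset gives zero CSD
  z <- compute_csd(synthetic_shifts(offsets = rep(0, 5)))
  expect_equal(z$csd_ppm[c(2, 4)], c(0, 0))
})

test_that("CSD is invariant under a common shift of observed and reference", {
  s <- synthetic_shifts()
  coil <- coil_reference()
  s2 <- s; s2$shift_ppm <- s$shift_ppm + 1.0
  coil2 <- coil
  coil2$table$shift_ppm <- coil$table$shift_ppm + 1.0
  expect_equal(compute_csd(s2, coil2)$csd_ppm, compute_csd(s, coil)$csd_ppm)
})

test_that("valine CSD ranges of the study tables match their printed spans", {
  ha <- summarize_csd(csd_halpha_table(), residues = c(2, 4))
  expect_equal(ha$min, 0.09)
  expect_equal(ha$max, 0.22)
  expect_true(ha$sign_consistent)
  expect_equal(ha$n, 16)
  ca <- summarize_csd(csd_calpha_table(), residues = c(2, 4))
  expect_equal(ca$min, -2.5)
  expect_equal(ca$max, -1.6)
  expect_true(ca$sign_consistent)
  # single entry: min = max
  one <- summarize_csd(data.frame(residue_index = 2, csd_ppm = 0.13),
                       residues = 2)
  expect_equal(one$min, one$max)
  expect_error(summarize_csd(data.frame(residue_index = 2, csd_ppm = 0.13),
                             residues = 3), "no CSD entries")
})

test_that("temperature coefficients recover known slopes", {
  temps <- c(271, 285, 298)
  tc <- temp_coefficient(temps, 8.5 - 0.0078 * (temps - 271))
  expect_equal(tc$slope_ppb_K, -7.8, tolerance = 1e-9)
  expect_equal(tc$n_points, 3L)
  # constant shift: zero slope
  expect_equal(temp_coefficient(temps, rep(7.9, 3))$slope_ppb_K, 0)
  # noisy series: recovery within 0.5 ppb/K (seeded)
  set.seed(12)
  t6 <- seq(271, 311, by = 8)
  noisy <- 8.2 - 0.0063 * t6 + stats::rnorm(6, sd = 0.001)
  expect_lt(abs(temp_coefficient(t6, noisy)$slope_ppb_K - (-6.3)), 0.5)
  expect_error(temp_coefficient(298, 8.5), "2 distinct temperatures")
  expect_error(temp_coefficient(c(298, 298), c(8.5, 8.4)),
               "2 distinct temperatures")
})

test_that("hydrogen-bond classes partition the slope axis with strict bounds", {
  expect_identical(classify_hbond(-4.0), "hbonded-candidate")
  expect_identical(classify_hbond(-7.8), "exposed")
  expect_identical(classify_hbond(-5.2), "intermediate")
  expect_identical(classify_hbond(-4.5), "intermediate")  # boundary
  expect_identical(classify_hbond(-6.0), "intermediate")  # boundary
  # total and deterministic over a grid; the three classes partition it
  grid <- seq(-12, 2, by = 0.1)
  cls <- vapply(grid, classify_hbond, character(1))
  expect_true(all(cls %in% c("hbonded-candidate", "intermediate", "exposed")))
  expect_identical(cls[grid > -4.5], rep("hbonded-candidate", sum(grid > -4.5)))
  expect_identical(cls[grid < -6], rep("exposed", sum(grid < -6)))
  tc <- temp_coefficient(c(271, 298), c(8.5, 8.5 - 0.0078 * 27))
  expect_identical(classify_hbond(tc), "exposed")
})

test_that("chi1 rotamer calls follow the coupling thresholds", {
  expect_identical(classify_chi1(2.5), "gauche-dominated")
  expect_identical(classify_chi1(7.0), "mixed")
  expect_identical(classify_chi1(12), "anti-dominated")
  expect_identical(classify_chi1(5), "mixed")    # boundary
  expect_identical(classify_chi1(10), "mixed")   # boundary
  expect_error(classify_chi1(-1), "positive")
  # beta-branched central residues (Thr, (2S,3S)-CF3-Thr) call gauche;
  # the CF3-Thr couplings are the smallest of all
  t4 <- jhahb_table()
  central <- t4[t4$residue_index == 3, ]
  calls <- vapply(central$j_hz, classify_chi1, character(1))
  expect_identical(central$peptide[calls == "gauche-dominated"],
                   c("2a", "4a", "2b", "4b"))
  expect_identical(central$peptide[order(central$j_hz)][1:2], c("4b", "4a"))
})

test_that("periodicity scan flags residues protected relative to both neighbors", {
  t5 <- tempco_table()
  p4a <- t5[t5$peptide == "4a", ]
  fl <- periodicity_scan(p4a$residue_index, p4a$slope_ppb_K)
  expect_true(4 %in% fl)
  # monotone series: nothing flagged
  expect_length(periodicity_scan(1:5, c(-4, -5, -6, -7, -8)), 0)
  # margin above the maximum contrast: nothing flagged
  expect_length(periodicity_scan(p4a$residue_index, p4a$slope_ppb_K,
                                 margin = 10), 0)
  expect_error(periodicity_scan(1:2, c(-4, -5)), "3 residues")
})

test_that("across all systems, Val4 is flagged only in the 4-series", {
  t5 <- tempco_table()
  val4 <- vapply(unique(t5$peptide), function(p) {
    d <- t5[t5$peptide == p, ]
    4L %in% periodicity_scan(d$residue_index, d$slope_ppb_K)
  }, logical(1))
  expect_identical(names(val4)[val4], c("4a", "4b"))
})
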