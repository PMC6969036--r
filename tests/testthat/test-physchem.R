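test_that("ionizable composition counts side chains and termini", {
  comp <- ionizable_composition(S3FLAG)
  counts <- setNames(comp$count, comp$group)
  expect_equal(counts[["D"]], 11)
  expect_equal(counts[["K"]], 4)
  expect_equal(counts[["H"]], 2)
  expect_equal(counts[["Y"]], 3)
  expect_equal(counts[["Nterm"]], 1)
  expect_equal(counts[["Cterm"]], 1)
  expect_equal(sum(counts[c("E", "C", "R")]), 0)

  ha <- ionizable_composition(HA_TAG)
  ha_counts <- setNames(ha$count, ha$group)
  expect_equal(ha_counts[["D"]], 2)   # Y-P-Y-D-V-P-D-Y-A
  expect_equal(ha_counts[["Y"]], 3)

  none <- ionizable_composition("GAVLIPFWM", n_term = FALSE, c_term = FALSE)
  expect_equal(sum(none$count), 0)
})

test_that("invalid residues are rejected naming the position; lenient mode warns", {
  expect_error(ionizable_composition("ACDX"), "position 4")
  expect_error(net_charge("", ph = 7), "empty")
  expect_warning(
    comp <- ionizable_composition("ACDX", lenient = TRUE),
    "non-ionizable"
  )
  expect_equal(sum(comp$count[comp$group == "D"]), 1)
  # lower-case input is upper-cased, not rejected
  expect_equal(net_charge("dykddddk", 7), net_charge("DYKDDDDK", 7))
})

test_that("net charge reproduces hand Henderson-Hasselbalch sums", {
  # s3Flag printed anchor: strong net negative charge at pH 7.4
  expect_equal(net_charge(S3FLAG, 7.4), -7.0, tolerance = 0.15 / 7)
  # hand sum over 11 D, 4 K, 2 H, 3 Y plus termini at pH 6.6
  expect_equal(net_charge(S3FLAG, 6.6), -6.09, tolerance = 0.05 / 6)
  # glycine pentapeptide: termini only
  g5 <- 1 / (1 + 10^(7 - 8)) - 1 / (1 + 10^(3.1 - 7))
  expect_equal(net_charge("GGGGG", 7.0), g5, tolerance = 1e-12)
  expect_equal(g5, -0.091, tolerance = 1e-2)
  # no ionizable groups, termini disabled: exactly zero at any pH
  expect_identical(net_charge("GAVLIPFWM", c(0, 3, 7, 14),
                              n_term = FALSE, c_term = FALSE),
                   rep(0, 4))
  expect_error(net_charge(S3FLAG, -1), "\\[0, 14\\]")
  expect_error(net_charge(S3FLAG, 14.5), "\\[0, 14\\]")
})

test_that("net charge agrees with an independent residue-loop oracle", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_peptide(sample(3:40, 1))
    ph <- runif(1, 0, 14)
    expect_equal(net_charge(s, ph), hh_oracle(s, ph), tolerance = 1e-12)
  }
})

test_that("charge curves are monotone and carry pI metadata", {
  prof <- charge_curve(S3FLAG, ph = c(6.6, 7.03, 7.4))
  expect_s3_class(prof, "charge_profile")
  expect_true(all(prof$net_charge <= -6.0))
  expect_true(all(diff(prof$net_charge) < 0))
  expect_equal(attr(prof, "pI"), 4.48, tolerance = 1e-2)

  one <- charge_curve("GAVLIPFWM", ph = 7, n_term = FALSE, c_term = FALSE)
  expect_equal(nrow(one), 1L)
  expect_true(is.na(attr(one, "pI")))

  polyk <- charge_curve(strrep("K", 8))
  expect_gt(polyk$net_charge[1], 8.9)            # 8 K + N-term at pH 0
  expect_lt(abs(polyk$net_charge[nrow(polyk)] + 1), 0.02)  # C-term acid only

  expect_error(charge_curve(S3FLAG, ph = numeric(0)), "empty")
  expect_error(charge_curve(S3FLAG, ph = c(7, 6)), "increasing")
})

test_that("charge is non-increasing in pH for random peptides", {
  set.seed(22)
  grid <- seq(0, 14, by = 0.5)
  for (i in 1:100) {
    s <- random_peptide(sample(5:60, 1))
    q <- net_charge(s, grid)   # termini enabled: at least two ionizable groups
    expect_true(all(diff(q) < 0))
  }
})

test_that("boundary charges approach the ionizable-group counts", {
  # evaluated at the ends of [0,14]; arginine (pKa 12) is excluded because
  # its protonation is still 1% short of complete at pH 14
  set.seed(33)
  for (i in 1:20) {
    s <- random_peptide(8, exclude = "R")
    comp <- ionizable_composition(s)
    n_basic <- sum(comp$count[comp$sign > 0])
    n_acid <- sum(comp$count[comp$sign < 0])
    expect_equal(net_charge(s, 0), n_basic, tolerance = 1.5e-3 / max(n_basic, 1))
    expect_equal(net_charge(s, 14), -n_acid, tolerance = 1.5e-3 / max(n_acid, 1))
  }
})

test_that("bisection pI matches printed anchors and the grid-scan oracle", {
  expect_equal(isoelectric_point(S3FLAG), 4.48, tolerance = 0.15 / 4.48)
  expect_equal(isoelectric_point(HA_TAG), 3.53, tolerance = 0.15 / 3.53)
  # lysine alone: two basic groups (8.0, 10.0) against the C-term acid
  expect_equal(isoelectric_point("K"), 9.0, tolerance = 1e-3)
  set.seed(44)
  for (i in 1:100) {
    s <- random_peptide(sample(3:30, 1))
    expect_equal(isoelectric_point(s), grid_pi(s), tolerance = 2e-3 / 7,
                 label = s)
  }
})

test_that("pI is the midpoint of a single acid/base pKa pair", {
  # D (4.4) against K (10.0), termini disabled: pI = 7.2
  expect_equal(isoelectric_point("DK", n_term = FALSE, c_term = FALSE),
               (4.4 + 10.0) / 2, tolerance = 1e-3)
  m <- pka_set(c(D = 3.0, E = 4.4, H = 6.5, C = 8.5, Y = 10, K = 11.0, R = 12),
               n_term_pka = 8, c_term_pka = 3.1)
  expect_equal(isoelectric_point("DK", pka = m, n_term = FALSE, c_term = FALSE),
               (3.0 + 11.0) / 2, tolerance = 1e-3)
})

test_that("pI-undefined is a distinct error class", {
  err <- tryCatch(isoelectric_point("DDDD", n_term = FALSE, c_term = FALSE),
                  error = function(e) e)
  expect_s3_class(err, "standr_pi_undefined")
  err2 <- tryCatch(isoelectric_point("DDX?"), error = function(e) e)
  expect_false(inherits(err2, "standr_pi_undefined"))
})

test_that("charge is additive over concatenation with termini disabled", {
  set.seed(55)
  for (i in 1:20) {
    a <- random_peptide(sample(3:20, 1))
    b <- random_peptide(sample(3:20, 1))
    ph <- runif(1, 0, 14)
    expect_equal(
      net_charge(paste0(a, b), ph, n_term = FALSE, c_term = FALSE),
      net_charge(a, ph, n_term = FALSE, c_term = FALSE) +
        net_charge(b, ph, n_term = FALSE, c_term = FALSE),
      tolerance = 1e-12
    )
  }
})

test_that("pKa set validation and serialization round-trip", {
  expect_error(pka_set(c(D = 4.4), 8, 3.1), "exactly")
  expect_error(pka_set(c(D = 4.4, E = 4.4, H = 6.5, C = 8.5, Y = 10,
                         K = 10, R = 15), 8, 3.1), "\\(0, 14\\)")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pka(pka_default(), path)
  back <- read_pka(path)
  expect_equal(back$side_chain_pka, pka_default()$side_chain_pka)
  expect_equal(back$n_term_pka, 8.0)
  expect_equal(back$c_term_pka, 3.1)
  expect_equal(net_charge(S3FLAG, 7.4, pka = back), net_charge(S3FLAG, 7.4))
})

test_that("calibration report flags a drifted pKa set", {
  rep_ok <- calibrate_pka(pka_default())
  expect_true(all(rep_ok$pass))
  drifted <- pka_set(c(D = 7.0, E = 4.4, H = 6.5, C = 8.5, Y = 10,
                       K = 10, R = 12), n_term_pka = 8, c_term_pka = 3.1,
                     name = "drifted-Asp")
  rep_bad <- calibrate_pka(drifted)
  expect_false(all(rep_bad$pass))
  expect_false(rep_bad$pass[rep_bad$anchor == "s3Flag charge @pH 7.4"])
  empty <- calibrate_pka(pka_default(), anchors = pka_anchors()[0, ])
  expect_equal(nrow(empty), 0L)
})
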