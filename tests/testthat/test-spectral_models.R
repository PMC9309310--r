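# Descriptor regression models and Govardovskii templates.

table2_rh2 <- data.frame(
  id = c("Rh2-1", "Rh2-2", "Rh2-3", "Rh2-4"),
  torsion15 = c(3.64, 3.06, 0.41, 0.84),
  rmsf = c(0.79, 0.76, 1.12, 1.1),
  printed = c(471.5, 475.5, 511.2, 506.4))

test_that("the two-term RH2 model reproduces its published example outputs", {
  for (i in seq_len(nrow(table2_rh2))) {
    d <- descriptor_set(torsion15_median = table2_rh2$torsion15[i],
                        rmsf_auc = table2_rh2$rmsf[i],
                        pigment_id = table2_rh2$id[i])
    pr <- predict_rh2(d)
    expect_equal(pr$lambda_max, table2_rh2$printed[i], tolerance = 0.5 /
                   table2_rh2$printed[i])
    expect_equal(pr$method, "regression")
  }
  # intercept and direct-arithmetic oracle points
  expect_equal(predict_rh2(descriptor_set(torsion15_median = 0,
                                          rmsf_auc = 0))$lambda_max,
               475.628)
  expect_equal(predict_rh2(descriptor_set(torsion15_median = 1,
                                          rmsf_auc = 1))$lambda_max,
               475.628 - 8.720 + 34.925)
})

test_that("the three-term SWS2 model reproduces its published output", {
  d <- descriptor_set(angle3_median = 132.33, torsion3_median = 2.14,
                      torsion12_median = -5.1, pigment_id = "Sws2")
  expect_equal(predict_sws2(d)$lambda_max, 420.04, tolerance = 0.05 / 420)
  # raw intercept is returned but flagged out of range
  d0 <- predict_sws2(descriptor_set(angle3_median = 0, torsion3_median = 0,
                                    torsion12_median = 0))
  expect_equal(d0$lambda_max, 2677.5348)
  expect_true("out_of_range" %in% d0$flags)
  d100 <- predict_sws2(descriptor_set(angle3_median = 100,
                                      torsion3_median = 0,
                                      torsion12_median = 0))
  expect_equal(d100$lambda_max, 972.3348)
  expect_true("out_of_range" %in% d100$flags)
})

test_that("model evaluation is affine in the descriptors", {
  d1 <- descriptor_set(torsion15_median = 3.64, rmsf_auc = 0.79)
  d2 <- descriptor_set(torsion15_median = 0.41, rmsf_auc = 1.12)
  for (a in c(0, 0.25, 0.5, 1)) {
    mix <- descriptor_set(
      torsion15_median = a * 3.64 + (1 - a) * 0.41,
      rmsf_auc = a * 0.79 + (1 - a) * 1.12)
    expect_equal(predict_rh2(mix)$lambda_max,
                 a * predict_rh2(d1)$lambda_max +
                   (1 - a) * predict_rh2(d2)$lambda_max,
                 tolerance = 1e-9)
  }
})

test_that("missing descriptors are reported by name", {
  expect_error(predict_rh2(descriptor_set(torsion15_median = 1)),
               "rmsf_auc")
  expect_error(predict_sws2(descriptor_set(angle3_median = 130)),
               "torsion3")
})

test_that("the packaged descriptor table predicts through class dispatch", {
  ds <- read_descriptors_tsv(extdata("salmon_md_descriptors.tsv"))
  preds <- predict_from_descriptors(ds)
  lam <- vapply(preds, function(p) p$lambda_max, numeric(1))
  names(lam) <- vapply(preds, function(p) p$pigment_id, character(1))
  expect_equal(unname(lam["Sws2"]), 420.04, tolerance = 1e-3)
  rh2 <- lam[paste0("Rh2-", 1:4)]
  expect_true(all(abs(rh2 - c(471.5, 475.5, 511.2, 506.4)) < 0.5))
  # the published "almost 40 nm" span across the RH2 class
  expect_gte(diff(range(rh2)), 39)
  expect_lte(diff(range(rh2)), 40)
})

test_that("Govardovskii template peaks at 1 and matches the oracle", {
  for (lmax in c(360, 420, 471.5, 509, 560)) {
    sp <- govardovskii_template(lmax, 300:700)
    expect_equal(max(sp$absorbance), 1)
    # the composite maximum sits on (or within the beta-band 1 nm pull of)
    # the grid point nearest lambda-max
    expect_lte(abs(sp$wavelength_nm[which.max(sp$absorbance)] -
                     round(lmax)), 1)
    # dual-implementation check (same normalization applied to the oracle)
    oracle <- oracle_govardovskii(300:700, lmax)
    oracle <- oracle / max(oracle)
    expect_equal(sp$absorbance, oracle, tolerance = 1e-9)
    # strictly decreasing long-wave limb
    limb <- sp$absorbance[sp$wavelength_nm > lmax + 1]
    expect_true(all(diff(limb) < 0))
    # value at lambda_max/0.922 agrees with the oracle to 1e-9 even
    # between grid points
    l922 <- lmax / 0.922
    g2 <- sort(c(300, l922, 700))
    sp2 <- govardovskii_template(lmax, g2)
    expect_equal(sp2$absorbance[sp2$wavelength_nm == l922] *
                   max(oracle_govardovskii(g2, lmax)),
                 oracle_govardovskii(l922, lmax), tolerance = 1e-9)
  }
})

test_that("the alpha band alone is unimodal; the beta band adds the cis bump", {
  for (lmax in c(360, 420, 506, 560)) {
    s <- govardovskii_template(lmax, 300:700, beta_band = FALSE)$absorbance
    signs <- sign(diff(s))
    flips <- sum(diff(signs[signs != 0]) != 0)
    expect_equal(flips, 1)
    # alpha band peaks exactly on the grid point nearest lambda-max
    sp <- govardovskii_template(lmax, 300:700, beta_band = FALSE)
    expect_equal(sp$wavelength_nm[which.max(sp$absorbance)], round(lmax))
  }
  # for a green/red pigment the full template has the secondary UV bump
  full <- govardovskii_template(509, 300:700)$absorbance
  w <- 300:700
  uv <- full[w >= 330 & w <= 380]
  expect_gt(max(uv), full[w == 395])  # genuine local maximum
  expect_lt(max(uv), 0.3)             # but far below the main band
})

test_that("off-grid lambda-max warns but still returns a spectrum", {
  expect_warning(sp <- govardovskii_template(360, 400:700), "cover")
  expect_s3_class(sp, "absorbance_spectrum")
  expect_equal(max(sp$absorbance), 1)
})

test_that("spectrum panel produces one normalized template per pigment", {
  lam <- read.delim(extdata("salmon_lambda_max.tsv"))
  panel <- spectrum_panel(setNames(lam$lambda_max_nm, lam$pigment_id))
  expect_equal(length(unique(panel$pigment_id)), 11)
  peaks <- vapply(split(panel, panel$pigment_id), function(df) {
    df$wavelength_nm[which.max(df$absorbance)]
  }, numeric(1))
  # the UV pigment's composite peak sits 1 nm short (beta band); the rest
  # peak exactly at their lambda-max
  expect_true(all(abs(peaks[lam$pigment_id] - lam$lambda_max_nm) <= 1))
  expect_equal(sum(peaks[lam$pigment_id] != lam$lambda_max_nm), 1)

  expect_equal(nrow(spectrum_panel(list())), 0)
  two <- spectrum_panel(c(a = 500, b = 500))
  expect_equal(two$absorbance[two$pigment_id == "a"],
               two$absorbance[two$pigment_id == "b"])
  expect_warning(
    spectrum_panel(list(list(pigment_id = "x", lambda_max = NA_real_))),
    "skipping")
})
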