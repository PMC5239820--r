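# printed reference values for the packaged octa-acid prediction sets
# (2-decimal table convention; computed-value agreement to one unit in the
# last printed digit, since the experimental column is itself rounded)
tab3 <- list(
  gaff_refined = list(
    OAMe = c(MAD = 0.82, MADTr = 0.82, AvErr = -0.47, R2 = 0.58),
    OAH = c(MAD = 1.02, MADTr = 0.52, AvErr = -1.02, R2 = 0.99),
    combined = c(MAD = 0.92, MADTr = 0.64, AvErr = -0.74, R2 = 0.88)),
  opls_refined = list(
    OAMe = c(MAD = 1.67, MADTr = 1.51, AvErr = 0.47, R2 = 0.48),
    OAH = c(MAD = 1.20, MADTr = 0.24, AvErr = -1.20, R2 = 0.99),
    combined = c(MAD = 1.44, MADTr = 1.31, AvErr = -0.37, R2 = 0.69)),
  gaff_submitted = list(
    OAMe = c(MAD = 3.60, MADTr = 1.11, AvErr = 3.60, R2 = 0.34),
    OAH = c(MAD = 2.05, MADTr = 0.44, AvErr = 2.05, R2 = 0.97),
    combined = c(MAD = 2.82, MADTr = 0.94, AvErr = 2.82, R2 = 0.73)))

test_that("the packaged prediction sets reproduce the published metric table", {
  for (set in names(tab3)) {
    tbl <- sampl5_predictions(set)
    expect_equal(nrow(tbl), 12)          # reference complex excluded
    for (grp in names(tab3[[set]])) {
      ref <- tab3[[set]][[grp]]
      expect_close(mad_err(tbl, grp), ref[["MAD"]])
      expect_close(mad_tr(tbl, grp), ref[["MADTr"]])
      expect_close(av_err(tbl, grp), ref[["AvErr"]])
      expect_close(r_squared(tbl, grp), ref[["R2"]])
    }
  }
})

test_that("the equal-affinity dummy predictor gives the published MADTr", {
  tbl <- sampl5_predictions("gaff_refined")
  expect_close(dummy_madtr(tbl, "OAMe"), 0.93)
  expect_close(dummy_madtr(tbl, "OAH"), 1.29)
  same <- prediction_table(letters[1:4], rep("X", 4), 1:4, rep(-5, 4))
  expect_equal(dummy_madtr(same, "X"), 0)
})

test_that("the reference complex is excluded unless requested", {
  with_ref <- sampl5_predictions("gaff_refined", include_reference = TRUE)
  expect_equal(nrow(with_ref), 13)
  expect_true("OAH-Gu2" %in% with_ref$system)
  expect_false("OAH-Gu2" %in% sampl5_predictions("gaff_refined")$system)
})

test_that("degenerate metric cases behave as defined", {
  tbl <- prediction_table(c("a", "b", "c"), rep("H", 3),
                          c(-5, -6, -7), c(-5, -6, -7))
  expect_equal(av_err(tbl, "H"), 0)
  expect_equal(mad_err(tbl, "H"), 0)
  one <- prediction_table("a", "H", -5, -6.5)
  expect_equal(mad_err(one, "H"), 1.5)
  expect_error(av_err(tbl, "nope"), "empty or unknown group")
})

test_that("R^2 is 1 on any exact line and errors on constant columns", {
  x <- c(-9, -7, -4, -2)
  up <- prediction_table(letters[1:4], rep("H", 4), 2 * x + 1, x)
  dn <- prediction_table(letters[1:4], rep("H", 4), -3 * x + 2, x)
  expect_equal(r_squared(up, "H"), 1)
  expect_equal(r_squared(dn, "H"), 1)   # sign is ignored
  flat <- prediction_table(letters[1:4], rep("H", 4), rep(1, 4), x)
  expect_error(r_squared(flat, "H"), "constant")
  expect_error(r_squared(prediction_table("a", "H", 1, 2), "H"), "at least 3")
})

test_that("metric identities hold on random tables", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    tbl <- prediction_table(paste0("s", 1:n),
                            sample(c("A", "B"), n, replace = TRUE),
                            rnorm(n, -5, 2), rnorm(n, -5, 2))
    for (grp in unique(tbl$host)) {
      # triangle bound: |e - mean(e)| <= |e| + |mean(e)| termwise
      expect_lte(mad_tr(tbl, grp),
                 mad_err(tbl, grp) + abs(av_err(tbl, grp)) + 1e-12)
      # exact translation invariance of MADTr
      shifted <- tbl
      shifted$dg_calc <- shifted$dg_calc + 11.3
      expect_equal(mad_tr(shifted, grp), mad_tr(tbl, grp))
    }
    # combined AvErr is the size-weighted mean of the per-group values
    groups <- unique(tbl$host)
    sizes <- vapply(groups, function(g) sum(tbl$host == g), numeric(1))
    per <- vapply(groups, function(g) av_err(tbl, g), numeric(1))
    expect_equal(av_err(tbl, "combined"), sum(sizes * per) / sum(sizes))
    # equal predictions make MADTr collapse onto the dummy MADTr
    const <- tbl
    const$dg_calc <- rep(-5, n)
    expect_equal(mad_tr(const, "combined"), dummy_madtr(const, "combined"))
  }
})

test_that("metric uncertainty responds linearly to the per-system errors", {
  tbl <- sampl5_predictions("gaff_refined")
  zero <- tbl
  zero$dg_err <- rep(0, nrow(zero))
  u0 <- metric_uncertainty(zero, n_rep = 50, seed = 1)
  expect_true(all(u0$sd == 0))
  u1 <- metric_uncertainty(tbl, n_rep = 400, seed = 2)
  doubled <- tbl
  doubled$dg_err <- 2 * doubled$dg_err
  u2 <- metric_uncertainty(doubled, n_rep = 400, seed = 3)
  sel <- u1$metric %in% c("MAD", "MADTr", "AvErr")
  ratio <- u2$sd[sel] / u1$sd[sel]
  expect_equal(mean(ratio), 2, tolerance = 0.25)
  # submitted set has no errors: must refuse
  expect_error(metric_uncertainty(sampl5_predictions("gaff_submitted")),
               "errors are required")
})

test_that("prediction tables reject duplicate ids", {
  expect_error(prediction_table(c("a", "a"), c("H", "H"), 1:2, 1:2),
               "duplicated")
})
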