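test_that("log transformation respects the censoring policy", {
  p <- potency_table(c("a", "b", "c"), rep("L", 3), c(100, 55.2, 100),
                     c("observed", "observed", "censored"))
  lt <- log_transform(p, "L", policy = "exclude")
  expect_equal(lt$log_ic50[["a"]], 2)
  expect_equal(lt$log_ic50[["b"]], 1.741939, tolerance = 1e-6)
  expect_false("c" %in% names(lt$log_ic50))
  expect_equal(lt$excluded$compound, "c")
  expect_match(lt$excluded$reason, "right-censored at 100")

  ab <- log_transform(p, "L", policy = "at_bound")
  expect_equal(ab$log_ic50[["c"]], 2)
  expect_equal(nrow(ab$excluded), 0)

  expect_error(log_transform(p, "nope"), "not present")
})

test_that("univariate OLS matches closed-form values and guards degeneracy", {
  f <- fit_linear(c(1, 2, 3), c(3, 5, 7))
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  f2 <- fit_linear(c(1, 2, 3), c(1, 3, 2))
  expect_equal(f2$r_squared, 0.25, tolerance = 1e-12)

  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)), "constant predictor")
  expect_error(fit_linear(c(1, 2), c(1, 2)), "n < 3")
  expect_error(fit_linear(1:3, 1:4), "lengths differ")
})

test_that("univariate R^2 equals the squared brute-force Pearson correlation", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    if (stats::var(x) == 0) next
    f <- fit_linear(x, y)
    expect_equal(f$r_squared, brute_pearson(x, y)^2, tolerance = 1e-12)
  }
})

test_that("R^2 is invariant under affine changes of response and predictor", {
  set.seed(29)
  for (rep in 1:10) {
    ic50_uM <- stats::rlnorm(8, log(40), 0.6)
    bw <- stats::rnorm(8, -8.5, 0.3)
    base10 <- fit_linear(bw, log10(ic50_uM))$r_squared
    nat <- fit_linear(bw, log(ic50_uM))$r_squared
    molar <- fit_linear(bw, log10(ic50_uM * 1e-6))$r_squared
    shifted_x <- fit_linear(2.5 * bw + 7, log10(ic50_uM))$r_squared
    expect_equal(nat, base10, tolerance = 1e-12)
    expect_equal(molar, base10, tolerance = 1e-12)
    expect_equal(shifted_x, base10, tolerance = 1e-12)
  }
})

test_that("adding a predictor never decreases R^2", {
  set.seed(37)
  for (rep in 1:10) {
    n <- 9
    x1 <- stats::rnorm(n)
    x2 <- stats::rnorm(n)
    y <- 0.8 * x1 + stats::rnorm(n, 0, 0.5)
    uni <- fit_linear(x1, y)$r_squared
    biv <- fit_bivariate(x1, x2, y)$r_squared
    expect_gte(biv, uni - 1e-12)
  }
})

test_that("bivariate fits detect collinearity and exact planes", {
  x <- c(1, 2, 3, 4.5)
  expect_error(fit_bivariate(x, x, c(1, 2, 3, 5)), "collinear")
  expect_error(fit_bivariate(x, 2 * x + 1, c(1, 2, 3, 5)), "collinear")
  y <- 2 * x + 3 * c(0, 1, 0, 1) + 1
  f <- fit_bivariate(x, c(0, 1, 0, 1), y)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_bivariate(1:3, c(2, 1, 3), 1:3), "n < 4")
})

test_that("noiseless synthetic data give an all-ones BE_w row in the panel", {
  tr <- synthetic_truth(noise_sd = 0, seed = 12)
  pot <- gen_potency(tr)
  panel <- r2_panel(tr$bw_table, pot)
  expect_equal(unname(unclass(panel)["BE_w", ]), rep(1, 7), tolerance = 1e-9)
})

test_that("panel entries equal pairwise fit_linear results with exclusion accounting", {
  tr <- synthetic_truth(seed = 21, noise_sd = 0.15)
  pot <- gen_potency(tr)
  desc <- data.frame(compound = rownames(tr$bw_table),
                     TPSA = stats::runif(9, 60, 120),
                     HBD = sample(0:3, 9, replace = TRUE))
  panel <- r2_panel(tr$bw_table, pot, descriptors = desc)
  expect_equal(rownames(panel), c("BE_w", "TPSA", "HBD"))
  for (cl in colnames(panel)) {
    lt <- log_transform(pot, cl)
    common <- intersect(rownames(tr$bw_table), names(lt$log_ic50))
    n_av <- sum(pot$cell_line == cl)
    expect_equal(length(common) + nrow(lt$excluded), n_av)
    if (length(common) >= 3) {
      ref <- fit_linear(unclass(tr$bw_table)[common, cl], lt$log_ic50[common])
      expect_equal(unclass(panel)["BE_w", cl], ref$r_squared, tolerance = 1e-12)
      expect_equal(attr(panel, "n_used")["BE_w", cl], length(common))
    }
  }
  expect_true(all(unclass(panel) >= 0 & unclass(panel) <= 1, na.rm = TRUE))
})

test_that("cells with too few usable compounds are NA with a recorded reason", {
  # one cell line almost fully censored
  p <- potency_table(c("a", "b", "c", "a", "b", "c"),
                     rep(c("L1", "L2"), each = 3),
                     c(10, 20, 40, 100, 100, 15),
                     c(rep("observed", 3), "censored", "censored", "observed"))
  bw <- weighted_energy_table(matrix(c(-8, -8.5, -9, -8, -8.5, -9), 3, 2,
                                     dimnames = list(c("a", "b", "c"), c("L1", "L2"))))
  panel <- r2_panel(bw, p)
  expect_false(is.na(unclass(panel)["BE_w", "L1"]))
  expect_true(is.na(unclass(panel)["BE_w", "L2"]))
  expect_match(attr(panel, "missing_reasons")[["BE_w|L2"]], "1 usable")
})

test_that("bw_qsar fits per cell line and its methods are coherent", {
  tr <- synthetic_truth(seed = 33, noise_sd = 0.1)
  pot <- gen_potency(tr)
  fit <- bw_qsar(tr$matrix, tr$panel, pot)
  expect_s3_class(fit, "bw_qsar")
  expect_equal(colnames(coef(fit)), c("(Intercept)", "x"))
  expect_equal(nrow(coef(fit)), length(fit$fits))

  pred <- predict(fit)
  cl <- names(fit$fits)[1]
  f <- fit$fits[[cl]]
  expect_equal(unname(pred[f$compounds, cl]), unname(f$fitted), tolerance = 1e-12)
  res <- residuals(fit)
  expect_equal(length(res), length(fit$fits))
  expect_equal(unname(res[[cl]]), unname(f$residuals))

  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "potency_table")
  sims_again <- simulate(fit, nsim = 2, seed = 99)
  expect_identical(sims[[1]]$value, sims_again[[1]]$value)

  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("R\\^2 panel", out)))
})

test_that("bivariate BE_w + TPSA fits nest above the univariate model", {
  tr <- synthetic_truth(seed = 41, noise_sd = 0.2)
  pot <- gen_potency(tr)
  set.seed(42)
  desc <- data.frame(compound = rownames(tr$bw_table),
                     TPSA = stats::runif(9, 60, 120))
  fit <- bw_qsar(tr$matrix, tr$panel, pot, descriptors = desc)
  expect_false(is.null(fit$bivariate))
  for (cl in names(fit$bivariate)) {
    uni_same_rows <- fit_linear(
      unclass(fit$bw_table)[fit$bivariate[[cl]]$compounds, cl],
      fit$fits[[cl]]$fitted[match(fit$bivariate[[cl]]$compounds, fit$fits[[cl]]$compounds)] +
        fit$fits[[cl]]$residuals[match(fit$bivariate[[cl]]$compounds, fit$fits[[cl]]$compounds)])
    expect_gte(fit$bivariate[[cl]]$r_squared, uni_same_rows$r_squared - 1e-12)
  }
})
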