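test_that("a degenerate profile reproduces the matrix column exactly", {
  m <- table3()
  for (iso in colnames(m)) {
    w <- stats::setNames(as.numeric(colnames(m) == iso), colnames(m))
    prof <- expression_profile(w)
    expect_identical(unname(weighted_energy(m, prof)), unname(unclass(m)[, iso]))
  }
  prof1 <- expression_profile(stats::setNames(c(1, rep(0, 8)), colnames(m)))
  expect_identical(weighted_energy(m, prof1)[["5"]], -9.32)
})

test_that("the uniform profile gives the arithmetic row mean", {
  m <- table3()
  bw <- weighted_energy(m, uniform_profile(colnames(m)))
  expect_equal(bw[["4"]], -8.575556, tolerance = 1e-6)
  expect_equal(unname(bw), unname(rowMeans(unclass(m))))
})

test_that("identical columns collapse to the common vector for any profile", {
  v <- c(a = -9.1, b = -7.3, c = -8.8)
  m <- binding_matrix(cbind(i1 = v, i2 = v, i3 = v))
  set.seed(5)
  for (rep in 1:10) {
    g <- stats::rgamma(3, 1)
    prof <- expression_profile(stats::setNames(g / sum(g), colnames(m)))
    expect_equal(unname(weighted_energy(m, prof)), unname(v), tolerance = 1e-12)
  }
})

test_that("weighted energies stay inside row bounds and respect permutations", {
  set.seed(17)
  for (rep in 1:15) {
    m <- gen_binding_matrix(n_compounds = 6, isotype_ids = 5, seed = rep)
    g <- stats::rgamma(5, 1)
    prof <- expression_profile(stats::setNames(g / sum(g), colnames(m)))
    bw <- weighted_energy(m, prof)
    expect_true(all(bw >= apply(unclass(m), 1, min) - 1e-12))
    expect_true(all(bw <= apply(unclass(m), 1, max) + 1e-12))
    perm <- sample(ncol(m))
    mp <- binding_matrix(unclass(m)[, perm])
    pp <- expression_profile(prof[perm])
    expect_equal(weighted_energy(mp, pp), bw, tolerance = 1e-12)
  }
})

test_that("isotype label mismatches error unless restriction is requested", {
  m <- tiny_matrix()
  prof <- expression_profile(c(i1 = 0.5, i9 = 0.5))
  expect_error(weighted_energy(m, prof), "i9")
  # restricted: renormalize over the intersection -> all weight on i1
  bw <- weighted_energy(m, prof, restrict = TRUE)
  expect_equal(unname(bw), unclass(m)[, "i1"], ignore_attr = TRUE)
})

test_that("panel weighting equals column-wise weighting and matrix products", {
  m <- gen_binding_matrix(n_compounds = 7, isotype_ids = 6, seed = 3)
  panel <- gen_profiles(4, colnames(m), seed = 4)
  bw <- weighted_energy_panel(m, panel)
  expect_s3_class(bw, "weighted_energy_table")
  for (cl in colnames(panel)) {
    prof <- expression_profile(stats::setNames(panel[, cl], rownames(panel)))
    expect_equal(unclass(bw)[, cl], weighted_energy(m, prof), tolerance = 1e-14)
  }
  # brute-force oracle: plain matrix multiply
  expect_equal(unclass(bw), unclass(m) %*% unclass(panel)[colnames(m), ],
               tolerance = 1e-14, ignore_attr = TRUE)
  # degenerate panel copies matrix columns
  degs <- lapply(1:6, function(i) expression_profile(
    stats::setNames(as.numeric(seq_len(6) == i), colnames(m)),
    cell_line = paste0("L", i)))
  bw_deg <- weighted_energy_panel(m, expression_panel(degs))
  expect_equal(unclass(bw_deg), unclass(m), tolerance = 0, ignore_attr = TRUE)
})

test_that("midpoint weights are recovered exactly from a 2x2 system", {
  rec <- recover_weights(tiny_matrix(), c(c1 = -9, c2 = -7))
  expect_equal(unname(rec$weights), c(0.5, 0.5), tolerance = 1e-9)
  expect_lt(rec$residual_max, 1e-9)
  expect_true(rec$feasible)
})

test_that("targets below every row minimum are flagged infeasible", {
  m <- tiny_matrix()  # row ranges [-10,-8] and [-8,-6]
  rec <- recover_weights(m, c(c1 = -12, c2 = -10))
  expect_false(rec$feasible)
  expect_gt(rec$residual_max, 0)
  hc <- hull_check(m, c(c1 = -12, c2 = -10))
  expect_false(any(hc$within_bounds))
  expect_equal(hc$excess, c(2, 2))
})

test_that("forward weighting then recovery returns the fitted column", {
  for (s in 1:8) {
    m <- gen_binding_matrix(n_compounds = 9, isotype_ids = 9, seed = 100 + s)
    set.seed(200 + s)
    g <- stats::rgamma(9, 1)
    w <- g / sum(g)
    bw <- drop(unclass(m) %*% w)
    rec <- recover_weights(m, stats::setNames(bw, rownames(m)))
    expect_lte(rec$residual_rms, 1e-6)
    expect_lte(max(abs(rec$fitted - bw)), 1e-6)
    expect_equal(sum(rec$weights), 1, tolerance = 1e-8)
    expect_true(all(rec$weights >= -1e-12))
  }
})

test_that("two-decimal rounding keeps recovery residuals within 0.02 kcal/mol", {
  for (s in 1:8) {
    m <- gen_binding_matrix(n_compounds = 9, isotype_ids = 9, seed = 300 + s)
    set.seed(400 + s)
    g <- stats::rgamma(9, 1)
    w <- g / sum(g)
    bw <- round(drop(unclass(m) %*% w), 2)
    mr <- binding_matrix(round(unclass(m), 2))
    rec <- recover_weights(mr, stats::setNames(bw, rownames(m)))
    expect_lte(rec$residual_max, 0.02)
    expect_lte(max(abs(rec$fitted - bw)), 0.02)
  }
})

test_that("the active-set solution matches an independent quadratic-program solver", {
  skip_if_not_installed("quadprog")
  for (s in 1:6) {
    m <- gen_binding_matrix(n_compounds = 8, isotype_ids = 5, seed = 500 + s)
    set.seed(600 + s)
    bw <- drop(unclass(m) %*% (function(g) g / sum(g))(stats::rgamma(5, 1))) +
      stats::rnorm(8, 0, 0.05)
    rec <- recover_weights(m, stats::setNames(bw, rownames(m)))
    E <- unclass(m)
    D <- crossprod(E) + diag(1e-10, ncol(E))
    qp <- quadprog::solve.QP(D, crossprod(E, bw),
                             cbind(rep(1, ncol(E)), diag(ncol(E))),
                             c(1, rep(0, ncol(E))), meq = 1)
    expect_equal(drop(E %*% rec$weights), drop(E %*% qp$solution),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("rank-deficient matrices yield a flagged minimum-norm minimizer", {
  v <- c(a = -9, b = -8, c = -7.5)
  m <- binding_matrix(cbind(i1 = v, i2 = v, i3 = c(-8, -7, -9)))
  rec <- recover_weights(m, stats::setNames(0.5 * v + 0.5 * c(-8, -7, -9), names(v)))
  expect_true(rec$nonunique)
  expect_lt(rec$residual_max, 1e-6)
  # duplicated columns share the weight equally under minimum norm
  expect_equal(rec$weights[["i1"]], rec$weights[["i2"]], tolerance = 1e-6)
})

test_that("hull screening reproduces the published inconsistency", {
  m <- table3()
  bw4 <- table4()
  hc <- hull_check(m, stats::setNames(unclass(bw4)[, "SW480"], rownames(bw4)))
  expect_false(hc$within_bounds[hc$compound == "4"])   # -8.10 above row max -8.21
  expect_true(hc$within_bounds[hc$compound == "10"])   # -8.48 inside [-8.78, -8.34]
  expect_false(hc$within_bounds[hc$compound == "20"])  # below row min -8.13
  # bw equal to a single matrix entry of its row is always inside
  hc2 <- hull_check(m, stats::setNames(unclass(m)[, 3], rownames(m)))
  expect_true(all(hc2$within_bounds))
})

test_that("diagnose surfaces out-of-hull entries as a warning, not an error", {
  expect_warning(d <- diagnose(table3(), table4()), "convex hull")
  expect_true(all(d$summary$n_out_of_hull >= 5))
  expect_true(all(!d$summary$feasible))
  expect_s3_class(d, "bw_diagnosis")
  # a self-consistent pair is quiet and feasible
  m <- gen_binding_matrix(seed = 9)
  panel <- gen_profiles(3, colnames(m), seed = 10)
  expect_no_warning(d2 <- diagnose(m, weighted_energy_panel(m, panel)))
  expect_true(all(d2$summary$feasible))
})
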