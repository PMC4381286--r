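# Binding/kinetics fitting and the derived thermodynamic quantities.

test_that("noiseless titrations are recovered essentially exactly", {
  ti <- gen_titration(kd = 62.5e-9, noise = 0, seed = 1)
  fit <- fit_binding(ti$series$ligand_conc, ti$series$signal,
                     enzyme_conc = 0.5e-6)
  expect_equal(unname(coef(fit)["kd"]), 62.5e-9, tolerance = 1e-3 * 1e-3)
  expect_equal(unname(coef(fit)["amplitude"]), -0.6, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["baseline"]), 1, tolerance = 1e-6)
  ## methods behave
  expect_equal(length(fitted(fit)), nrow(ti$series))
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_equal(predict(fit, newdata = ti$series$ligand_conc),
               ti$series$signal, tolerance = 1e-9)
  expect_output(print(fit), "binding fit")
  expect_output(print(summary(fit)), "RSS")
})

test_that("the depletion-aware fit approaches the hyperbolic limit when L >> E", {
  ## enzyme a thousand-fold below Kd: depletion negligible
  E <- 0.1e-9; kd <- 100e-9
  L <- c(5, 10, 25, 50, 100, 200, 400, 800, 1600) * 1e-9
  y <- 0.8 - 0.5 * L / (kd + L)
  quad <- fit_binding(L, y, enzyme_conc = E, model = "quadratic")
  hyp <- fit_binding(L, y, enzyme_conc = E, model = "hyperbolic")
  expect_equal(unname(coef(hyp)["kd"]), kd, tolerance = 1e-6)
  expect_equal(unname(coef(quad)["kd"]), unname(coef(hyp)["kd"]),
               tolerance = 1e-3)
})

test_that("binding fit recovers Kd within 5% at 1% noise (median of 20)", {
  errs <- vapply(1:20, function(seed) {
    ti <- gen_titration(kd = 62.5e-9, noise = 0.01, seed = seed)
    fit <- fit_binding(ti$series$ligand_conc, ti$series$signal, 0.5e-6)
    abs(coef(fit)["kd"] - 62.5e-9) / 62.5e-9
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("Michaelis-Menten fitting recovers planted parameters", {
  mm <- gen_mm(kcat = 5.3, km = 65.4e-6, noise = 0, seed = 1)
  fit <- fit_mm(mm$series$substrate_conc, mm$series$rate, enzyme_conc = 50e-9)
  expect_equal(unname(coef(fit)["kcat"]), 5.3, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["km"]), 65.4e-6, tolerance = 1e-9)
  ## half-saturation identity: v(Km) = kcat * E / 2
  expect_equal(predict(fit, newdata = 65.4e-6), 5.3 * 50e-9 / 2,
               tolerance = 1e-9)
  ## 2% noise, within 10% (median of 20 seeds)
  errs <- vapply(1:20, function(seed) {
    d <- gen_mm(noise = 0.02, seed = seed)
    f <- fit_mm(d$series$substrate_conc, d$series$rate, 50e-9)
    max(abs(coef(f)["kcat"] - 5.3) / 5.3, abs(coef(f)["km"] - 65.4e-6) / 65.4e-6)
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("fit bias shrinks monotonically as noise vanishes", {
  med_err <- vapply(c(0.02, 0.01, 0.005, 0), function(nz) {
    errs <- vapply(1:12, function(seed) {
      ti <- gen_titration(noise = nz, seed = seed)
      abs(coef(fit_binding(ti$series$ligand_conc, ti$series$signal,
                           0.5e-6))["kd"] - 62.5e-9) / 62.5e-9
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 1e-12))
  expect_lt(med_err[4], 1e-6)
})

test_that("series validation rejects malformed input", {
  expect_error(fit_binding(c(1, 2, 3) * 1e-6, c(1, 2, 3), 1e-6), "4 points")
  expect_error(fit_binding(c(3, 2, 1, 4) * 1e-6, c(1, 1, 1, 1), 1e-6),
               "strictly increasing")
  expect_error(fit_mm(c(1, 2, 3, 4) * 1e-6, c(1, 1, 1, -1) * 1e-9, 1e-9),
               "non-negative")
  expect_error(fit_mm(c(1, 2, 3, 4) * 1e-6, c(1, 1, 1, 1) * 1e-9, 0),
               "positive")
})

test_that("catalytic efficiency and fold changes reproduce reported values", {
  expect_equal(signif(efficiency(5.3, 65.4e-6), 2), 8.1e4)
  expect_equal(signif(efficiency(6.6, 139.4e-6), 2), 4.7e4)
  expect_equal(efficiency(0, 1e-6), 0)
  expect_error(efficiency(5, 0), "positive")

  e_wt <- efficiency(5.3, 65.4e-6)
  e_dh4 <- efficiency(8.5e-3, 441.5e-6)
  expect_equal(fold_change(e_wt, e_dh4, 2), 4200)
  expect_equal(fold_change(5.3, 1.5e-2, 3), 353)
  expect_equal(fold_change(3.2, 3.2), 1)
  expect_equal(fold_change(65.4, 139.4, 2, invert = TRUE), 2.1)
  expect_error(fold_change(0, 1), "positive")
})

test_that("binding free-energy differences behave thermodynamically", {
  expect_equal(delta_g(62.5e-9, 499e-9), 1.23, tolerance = 0.005)
  expect_equal(delta_g(65.4e-6, 139.4e-6), 0.45, tolerance = 0.005)
  expect_equal(delta_g(1e-6, 1e-6), 0)
  ## antisymmetry and additivity
  set.seed(3)
  for (i in 1:20) {
    k <- 10^runif(3, -9, -4)
    expect_equal(delta_g(k[1], k[2]), -delta_g(k[2], k[1]), tolerance = 1e-12)
    expect_equal(delta_g(k[1], k[3]),
                 delta_g(k[1], k[2]) + delta_g(k[2], k[3]), tolerance = 1e-12)
  }
  expect_error(delta_g(0, 1e-6), "positive")
})

test_that("zinc stoichiometry is inverse-predicted from the standard curve", {
  r <- zinc_ratio(data.frame(zn_conc = c(0, 10e-6), a500 = c(0, 0.5)),
                  sample_a500_background = 0, sample_a500_plateau = 0.465,
                  protein_conc = 10e-6)
  expect_equal(r$ratio, 0.93, tolerance = 1e-9)

  ## zero signal change: zero zinc
  r0 <- zinc_ratio(data.frame(zn_conc = c(0, 10e-6), a500 = c(0, 0.5)),
                   0.1, 0.1, 10e-6)
  expect_equal(r0$ratio, 0)

  ## non-zero intercept: verified against a grid search of the line
  std <- data.frame(zn_conc = seq(0, 12e-6, length.out = 5),
                    a500 = 0.05 + 4.8e4 * seq(0, 12e-6, length.out = 5))
  delta <- 0.05 + 4.8e4 * 7.3e-6
  r2 <- zinc_ratio(std, 0, delta, 10e-6)
  grid <- seq(0, 15e-6, by = 1e-10)
  zn_grid <- grid[which.min(abs((0.05 + 4.8e4 * grid) - delta))]
  expect_equal(r2$zn_conc, zn_grid, tolerance = 1e-9)

  ## outside the standard range: warning + flag
  expect_warning(rx <- zinc_ratio(data.frame(zn_conc = c(0, 1e-6),
                                             a500 = c(0, 0.05)),
                                  0, 0.2, 1e-6), "extrapolat")
  expect_true(rx$extrapolated)
  expect_error(zinc_ratio(data.frame(zn_conc = c(1e-6, 1e-6),
                                     a500 = c(0.1, 0.1)), 0, 0.05, 1e-6),
               "singular")
})

test_that("the full derived-quantity table reproduces printed precision", {
  pn <- paper_numbers()
  expect_true(all(pn$pass))
  expect_gt(nrow(pn), 25)
})
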