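test_that("identical rater columns over varying images give ICC = 1", {
  m <- cbind(1:6, 1:6, 1:6)
  rep <- icc_two_way(panel_from_matrix(m))
  expect_equal(rep$estimate, 1)
  expect_equal(unname(rep$components["ms_error"]), 0)
  expect_equal(unname(rep$components["ms_rater"]), 0)
})

test_that("ICC(2,1) matches the explicit two-way ANOVA oracle", {
  set.seed(11)
  m <- matrix(round(runif(18, 0, 8)), 6, 3)
  expect_equal(icc_two_way(panel_from_matrix(m))$estimate, oracle_icc21(m),
               tolerance = 1e-10)
  for (trial in 1:50) {
    n_img <- sample(3:12, 1); n_rat <- sample(2:6, 1)
    m <- matrix(runif(n_img * n_rat, 0, 10), n_img, n_rat)
    expect_equal(icc_two_way(panel_from_matrix(m))$estimate, oracle_icc21(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC approaches 1 as rater noise vanishes", {
  set.seed(21)
  latent <- rnorm(200, 4, 2)
  m <- sapply(1:5, function(j) latent + rnorm(200, 0, 0.01))
  expect_gt(icc_two_way(panel_from_matrix(m))$estimate, 0.98)
})

test_that("degenerate score panels raise an undefined-statistic error", {
  m <- matrix(5, 4, 3)
  expect_error(icc_two_way(panel_from_matrix(m)), "zero total variance")
  one_image <- panel_from_matrix(matrix(1:3, 1, 3))
  expect_error(icc_two_way(one_image), "at least 2 images")
})

test_that("ICC is invariant to shifting and positive rescaling", {
  set.seed(31)
  m <- matrix(runif(24, 0, 8), 8, 3)
  base <- icc_two_way(panel_from_matrix(m))$estimate
  expect_equal(icc_two_way(panel_from_matrix(m + 100))$estimate, base,
               tolerance = 1e-12)
  expect_equal(icc_two_way(panel_from_matrix(m * 3.7))$estimate, base,
               tolerance = 1e-12)
})

test_that("Fleiss' kappa matches the direct formula oracle", {
  m <- rbind(c("a", "a", "a"), c("a", "b", "b"), c("c", "c", "b"),
             c("b", "b", "b"))
  got <- fleiss_kappa(panel_from_matrix(m))
  expect_equal(got$estimate, oracle_fleiss(m), tolerance = 1e-12)
  # spreadsheet-style recomputation of the components
  expect_equal(unname(got$components["p_bar"]), mean(c(1, 1 / 3, 1 / 3, 1)),
               tolerance = 1e-12)
  expect_equal(unname(got$components["p_e"]),
               sum((c(4, 6, 2) / 12)^2), tolerance = 1e-12)

  set.seed(13)
  for (trial in 1:50) {
    m <- random_cat_panel(sample(2:10, 1), sample(2:7, 1), sample(2:5, 1))
    expect_equal(fleiss_kappa(panel_from_matrix(m))$estimate, oracle_fleiss(m),
                 tolerance = 1e-12)
  }
})

test_that("unanimous multi-category panels give kappa = 1", {
  m <- rbind(rep("a", 4), rep("b", 4), rep("a", 4))
  rep <- fleiss_kappa(panel_from_matrix(m))
  expect_equal(rep$estimate, 1)
  expect_equal(rep$band, "Perfect")
})

test_that("kappa is undefined when one category absorbs every rating", {
  m <- matrix("a", 4, 3)
  expect_error(fleiss_kappa(panel_from_matrix(m)), "undefined")
})

test_that("kappa is near zero for independent uniform labels", {
  set.seed(17)
  m <- matrix(sample(letters[1:4], 500 * 5, replace = TRUE), 500, 5)
  expect_lt(abs(fleiss_kappa(panel_from_matrix(m))$estimate), 0.05)
})

test_that("kappa is invariant to category relabelling and rater order", {
  set.seed(19)
  m <- random_cat_panel(12, 5, 3)
  base <- fleiss_kappa(panel_from_matrix(m))$estimate
  relab <- matrix(c(a = "z", b = "q", c = "m")[m], nrow(m), ncol(m))
  expect_equal(fleiss_kappa(panel_from_matrix(relab))$estimate, base,
               tolerance = 1e-12)
  expect_equal(fleiss_kappa(panel_from_matrix(m[, sample(ncol(m))]))$estimate,
               base, tolerance = 1e-12)
})

test_that("kappa increases with the raters' agreement probability", {
  means <- sapply(c(0.5, 0.7, 0.9), function(p) {
    mean(sapply(1:5, function(r) {
      sim <- simulate_panel(rater_sim_config(n_images = 200, p_agree = p),
                            seed = 1000 + r)
      fleiss_kappa(sim$severities)$estimate
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("interpretation bands follow the conventional tables", {
  expect_equal(interpret_band("icc", 0.8431), "Good")
  expect_equal(interpret_band("kappa", 0.4916), "Moderate")
  expect_equal(interpret_band("kappa", 1.00), "Perfect")
  expect_equal(interpret_band("icc", 0.3), "Poor")
  expect_equal(interpret_band("icc", 0.95), "Excellent")
  # shared endpoints go to the upper band
  expect_equal(interpret_band("icc", 0.75), "Good")
  expect_equal(interpret_band("icc", 0.9), "Excellent")
  expect_equal(interpret_band("kappa", 0.61), "Substantial")
  expect_equal(interpret_band("kappa", 0), "Equivalent to chance")
  expect_equal(interpret_band("kappa", -0.2), "Below chance")
  expect_error(interpret_band("kappa", 1.2), "exceed")
  expect_error(interpret_band("auc", 0.5), "Unknown statistic")
})

test_that("agreement reports serialise with components and summary line", {
  set.seed(23)
  m <- matrix(runif(30, 0, 8), 10, 3)
  rep <- icc_two_way(panel_from_matrix(m))
  path <- withr::local_tempfile(fileext = ".json")
  line <- write_agreement(rep, path)
  expect_match(line, sprintf("%.4f", rep$estimate), fixed = TRUE)
  back <- jsonlite::read_json(path)
  expect_equal(back$estimate, rep$estimate, tolerance = 1e-12)
  expect_equal(back$band, rep$band)
})
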