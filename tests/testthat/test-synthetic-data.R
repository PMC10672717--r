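test_that("artifact-free configuration yields empty masks", {
  cfg <- image_gen_config(width = 64, height = 48, n_highlights = c(0, 0),
                          n_dark = c(0, 0))
  frames <- generate_images(cfg, labels = "moderate", seed = 2)
  expect_equal(sum(frames$mask[[1]]), 0L)
  expect_identical(frames$clean[[1]], frames$corrupted[[1]])
  expect_equal(sum(hsv_artifact_mask(frames$corrupted[[1]])), 0L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- image_gen_config(width = 48, height = 48)
  a <- generate_images(cfg, labels = severity_levels3, seed = 5)
  b <- generate_images(cfg, labels = severity_levels3, seed = 5)
  expect_identical(a$clean, b$clean)
  expect_identical(a$corrupted, b$corrupted)
  expect_identical(lapply(a$mask, unclass), lapply(b$mask, unclass))
})

test_that("recovered HSV masks equal the ground truth pixel-for-pixel", {
  cfg <- image_gen_config(width = 96, height = 80)
  frames <- generate_images(cfg, labels = rep(severity_levels3, 7), seed = 8)
  for (i in seq_len(nrow(frames))) {
    got <- hsv_artifact_mask(frames$corrupted[[i]])
    expect_identical(unclass(got), unclass(frames$mask[[i]]))
  }
})

test_that("corruption only touches pixels inside the ground-truth mask", {
  frames <- generate_images(image_gen_config(width = 64, height = 64),
                            labels = c("moderate", "severe"), seed = 13)
  for (i in 1:2) {
    keep <- which(unclass(frames$mask[[i]]) == 0L)
    for (c in 1:3) {
      expect_identical(frames$corrupted[[i]][, , c][keep],
                       frames$clean[[i]][, , c][keep])
    }
  }
})

test_that("a tissue box overlapping the artifact ranges is refused", {
  expect_error(image_gen_config(tissue_s = c(80, 200)), "strictly inside")
  expect_error(image_gen_config(tissue_v = c(60, 200)), "strictly inside")
  expect_error(image_gen_config(highlight_s = c(0, 88)), "strictly below")
  expect_error(image_gen_config(dark_v = c(0, 64)), "strictly below")
})

test_that("class-conditional lesions are separable by a pixel-statistic probe", {
  set.seed(501)
  labs <- sample(rep(severity_levels3, times = c(155, 110, 35)))
  frames <- generate_images(image_gen_config(width = 64, height = 64),
                            labels = labs, seed = 501)
  feats <- t(vapply(frames$clean, function(img) {
    r <- img[, , 1]; g <- img[, , 2]
    c(mean(r), mean(g), mean(r > 200 & g < 80), mean(r < 130 & g < 60),
      stats::sd(g), unname(stats::quantile(g, 0.05)))
  }, numeric(6)))
  df <- data.frame(feats, label = frames$label)
  fit <- nnet::multinom(label ~ ., df, trace = FALSE)
  expect_gt(mean(predict(fit) == df$label), 0.9)
})

test_that("perfectly agreeing raters reproduce the latent truth exactly", {
  sim <- simulate_panel(rater_sim_config(n_images = 40, p_agree = 1), seed = 3)
  m <- matrix(sim$totals$label, nrow = 40)
  expect_true(all(m == sim$truth$total))
  expect_equal(fleiss_kappa(sim$severities)$estimate, 1)
  cv <- consensus_vote(sim$totals)
  expect_equal(cv$n_retained, 40L)
})

test_that("severity panels are the cutpoint mapping of the totals panels", {
  cp <- severity_cutpoints()
  sim <- simulate_panel(rater_sim_config(n_images = 30, p_agree = 0.7,
                                         cutpoints = cp), seed = 9)
  expect_equal(sim$severities$label,
               as.character(map_severity(sim$totals$label, cp)))
  sim3 <- simulate_panel(
    rater_sim_config(n_images = 30, p_agree = 0.7, severity_scale = "three"),
    seed = 9
  )
  expect_true(all(sim3$severities$label %in% severity_levels3))
})

test_that("latent totals stay inside their class cutpoint band", {
  sim <- simulate_panel(rater_sim_config(n_images = 300, p_agree = 0.8), seed = 15)
  cp <- severity_cutpoints()
  expect_true(all(
    as.character(merge_severity3(map_severity(sim$truth$total, cp))) ==
      as.character(sim$truth$class)
  ))
})

test_that("class frequencies match the configured prior", {
  cfg <- rater_sim_config(n_images = 1000)
  sim <- simulate_panel(cfg, seed = 77)
  obs <- table(factor(sim$truth$class, levels = severity_levels3))
  gof <- stats::chisq.test(as.vector(obs), p = cfg$class_prior)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated retention tracks the exact enumeration oracle", {
  rates <- vapply(1:5, function(r) {
    sim <- simulate_panel(rater_sim_config(n_images = 500, p_agree = 0.8),
                          seed = 600 + r)
    glance(consensus_vote(sim$totals, threshold = 3))$retention
  }, numeric(1))
  sim <- simulate_panel(rater_sim_config(n_images = 2000, p_agree = 0.8),
                        seed = 1234)
  p_by_total <- retention_probability(0:8, n_raters = 5, p_agree = 0.8,
                                      threshold = 3)
  expected <- mean(p_by_total[sim$truth$total + 1L])
  expect_lt(abs(mean(rates) - expected), 0.02)
})

test_that("rater error distribution is symmetric and sums to one", {
  p <- uceisr:::rater_error_probs(0.8)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["-1"]), unname(p["1"]))
  expect_equal(unname(p["-2"]), unname(p["2"]))
  expect_equal(unname(p["0"]), 0.8)
})

test_that("frames and panels write to disk in portable formats", {
  frames <- generate_images(image_gen_config(width = 32, height = 32),
                            labels = "severe", seed = 20)
  outd <- withr::local_tempdir()
  write_images(frames, outd)
  expect_true(file.exists(file.path(outd, "img0001.png")))
  expect_true(file.exists(file.path(outd, "img0001_mask.png")))
  expect_true(file.exists(file.path(outd, "labels.csv")))
  back <- read_rgb(file.path(outd, "img0001.png"))
  expect_identical(back, frames$corrupted[[1]])
})
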