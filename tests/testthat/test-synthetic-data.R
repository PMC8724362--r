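test_that("config invariants are enforced with messages naming the field", {
  expect_error(phantom_config(128, 96, cycle_amplitude = 0.7), "cycle_amplitude")
  expect_error(phantom_config(128, 96, clot_fraction = 0.9), "clot_fraction")
  expect_error(phantom_config(128, 96, rib_shadow_probability = 1.5),
               "rib_shadow_probability")
  expect_error(phantom_config(128, 96, heart_semiaxes = c(-3, 10)),
               "heart_semiaxes")
  expect_error(phantom_config(128, 96, heart_semiaxes = c(70, 10)),
               "heart_semiaxes")
  expect_error(generate_scan_set(test_config(), "a01", 9, "arrest"), "ics")
  expect_error(generate_scan_set(test_config(), "a01", 5, "sinus"), "state")
})

test_that("zero rib-shadow probability flags nothing; positive probability flags", {
  ss <- generate_scan_set(test_config(rib_shadow_probability = 0), "a01", 4, "arrest")
  expect_length(ss$images, 12)
  expect_false(any(vapply(ss$images, `[[`, logical(1), "rib_shadow_flag")))
  ss1 <- generate_scan_set(test_config(rib_shadow_probability = 1), "a01", 4, "arrest")
  expect_true(all(vapply(ss1$images, `[[`, logical(1), "rib_shadow_flag")))
})

test_that("degenerate motion (cycle_amplitude 0) gives 12 identical truth masks", {
  ss <- generate_scan_set(test_config(cycle_amplitude = 0), "a01", 5, "pre_arrest")
  for (k in 2:12) expect_identical(ss$truth_masks[[k]], ss$truth_masks[[1]])
  # and with motion the masks differ across the cycle
  ssm <- generate_scan_set(test_config(cycle_amplitude = 0.12), "a01", 5, "pre_arrest")
  areas <- vapply(ssm$truth_masks, sum, numeric(1))
  expect_gt(max(areas) - min(areas), 0)
})

test_that("identical config and seed reproduce scan sets bit-identically", {
  a <- generate_scan_set(test_config(), "a02", 6, "late_arrest", 1, seed = 11)
  b <- generate_scan_set(test_config(), "a02", 6, "late_arrest", 1, seed = 11)
  expect_identical(a, b)
  c <- generate_scan_set(test_config(), "a02", 6, "late_arrest", 1, seed = 12)
  expect_false(identical(a$images[[1]]$pixels, c$images[[1]]$pixels))
})

test_that("truth masks are one 4-connected component inside the sector", {
  sect <- sector_mask(128, 96)
  for (st in c("pre_arrest", "arrest", "late_arrest")) {
    ss <- generate_scan_set(test_config(), "a01", 4, st, 1, seed = 3)
    for (k in c(1, 4, 7, 10)) {
      truth <- ss$truth_masks[[k]]
      expect_true(all(sect[truth]))
      lab <- EBImage::bwlabel(EBImage::Image(t(truth) * 1))
      expect_equal(max(EBImage::imageData(lab)), 1)
    }
  }
})

test_that("late-arrest echogenic coverage tracks clot_fraction within 0.05", {
  cfg <- test_config(clot_fraction = 0.3)
  fracs <- vapply(1:20, function(s) {
    ss <- generate_scan_set(cfg, "a01", 5, "late_arrest", 1, seed = s)
    truth <- ss$truth_masks[[1]]
    sum(ss$images[[1]]$pixels > 100 & truth) / sum(truth)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.3), 0.05)
})

test_that("noiseless device tracing of a clot-free image fills to the truth exactly", {
  cfg <- test_config(tracer_jitter_sd = c(pre_arrest = 0, arrest = 0, late_arrest = 0))
  ss <- generate_scan_set(cfg, "a01", 5, "arrest")
  ov <- simulate_device_tracing(ss$images[[1]], ss$truth_masks[[1]], cfg)
  expect_identical(fill_tracing(ov, c(96, 128)), ss$truth_masks[[1]])
})

test_that("device tracing is deterministic in (image, config, seed)", {
  cfg <- test_config()
  ss <- generate_scan_set(cfg, "a03", 7, "pre_arrest")
  o1 <- simulate_device_tracing(ss$images[[2]], ss$truth_masks[[2]], cfg, seed = 5)
  o2 <- simulate_device_tracing(ss$images[[2]], ss$truth_masks[[2]], cfg, seed = 5)
  expect_identical(o1, o2)
  expect_error(simulate_device_tracing(ss$images[[1]], matrix(FALSE, 96, 128), cfg),
               "empty")
})

test_that("2 px jitter on a 200 px semiaxis keeps mean Dice at or above 0.95", {
  cfg <- phantom_config(512, 512, heart_center = c(162, 256.5),
                        heart_semiaxes = c(200, 120),
                        tracer_jitter_sd = c(pre_arrest = 2, arrest = 2, late_arrest = 2))
  ss <- generate_scan_set(cfg, "a01", 5, "arrest")
  truth <- ss$truth_masks[[1]]
  dice <- vapply(1:20, function(s) {
    ov <- simulate_device_tracing(ss$images[[1]], truth, cfg, seed = s)
    m <- fill_tracing(ov, dim(truth))
    sdi(confusion_areas(truth, m))
  }, numeric(1))
  expect_gte(mean(dice), 0.95)
})

test_that("reviewer tracings: exact at zero jitter, independent across ids, clot-inclusive", {
  cfg0 <- test_config(reviewer_jitter_sd = c(r1 = 0, r2 = 0))
  ss <- generate_scan_set(cfg0, "a01", 5, "arrest")
  ov <- simulate_reviewer_tracing(ss$images[[1]], ss$truth_masks[[1]], "r1", cfg0)
  expect_identical(fill_tracing(ov, c(96, 128)), ss$truth_masks[[1]])
  expect_error(simulate_reviewer_tracing(ss$images[[1]], ss$truth_masks[[1]],
                                         "r9", cfg0), "r9")

  cfg <- test_config()
  ssj <- generate_scan_set(cfg, "a01", 5, "arrest")
  a <- simulate_reviewer_tracing(ssj$images[[1]], ssj$truth_masks[[1]], "r1", cfg, seed = 4)
  b <- simulate_reviewer_tracing(ssj$images[[1]], ssj$truth_masks[[1]], "r2", cfg, seed = 4)
  expect_false(identical(a$curve_pixels, b$curve_pixels))

  # late arrest with zero jitter: the reviewer traces the full chamber, the
  # device omits the echogenic clot, so the reviewer area is larger
  cfgl <- test_config(tracer_jitter_sd = c(pre_arrest = 0, arrest = 0, late_arrest = 0),
                      reviewer_jitter_sd = c(r1 = 0))
  ssl <- generate_scan_set(cfgl, "a01", 5, "late_arrest")
  dev <- fill_tracing(simulate_device_tracing(ssl$images[[1]], ssl$truth_masks[[1]], cfgl),
                      c(96, 128))
  rev <- fill_tracing(simulate_reviewer_tracing(ssl$images[[1]], ssl$truth_masks[[1]],
                                                "r1", cfgl), c(96, 128))
  expect_gt(sum(rev), sum(dev))
})

test_that("generate_study emits 12 manifest rows per scan set and is reproducible", {
  cfg <- test_config()
  st <- generate_study(cfg, n_animals = 7,
                       states = c("pre_arrest", "arrest", "late_arrest"),
                       render = FALSE, seed = 2)
  expect_equal(nrow(st$manifest), 7 * 3 * 5 * 12)  # 105 scan sets, 1260 images
  st1 <- generate_study(cfg, n_animals = 1, states = "arrest", render = FALSE, seed = 2)
  expect_equal(nrow(st1$manifest), 5 * 12)
  st2 <- generate_study(cfg, n_animals = 1, states = "arrest", render = FALSE, seed = 2)
  expect_identical(st1$manifest, st2$manifest)
  expect_error(generate_study(cfg, n_animals = 1, states = character(0),
                              render = FALSE), "states")
})

test_that("generate_study writes rasters and a readable manifest", {
  cfg <- phantom_config(64, 48, rib_shadow_probability = 0)
  dir <- withr::local_tempdir()
  st <- generate_study(cfg, n_animals = 1, states = "arrest", ics = 4,
                       dir = dir, seed = 1)
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 12)
  img <- read_raster(file.path(dir, man$image_path[1]))
  expect_identical(img, st$scan_sets[[1]]$images[[1]]$pixels + 0)
  truth <- read_mask(file.path(dir, man$truth_path[1]))
  expect_identical(truth, st$scan_sets[[1]]$truth_masks[[1]])
})
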