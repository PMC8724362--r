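make_manifest <- function(n_animals = 7, states = c("pre_arrest", "arrest", "late_arrest"),
                          ics = 4:8, flag = FALSE) {
  rows <- expand.grid(plane_index = 1:12, scan_index = 1L, ics = ics,
                      state = states, animal_id = sprintf("a%02d", seq_len(n_animals)),
                      stringsAsFactors = FALSE)
  rows$rib_shadow_flag <- flag
  rows$image_path <- sprintf("%s_ics%d_%s_s%d_p%02d.png", rows$animal_id,
                             rows$ics, rows$state, rows$scan_index, rows$plane_index)
  rows
}

test_that("eligibility narrowing keeps exactly the LV/LVOT spaces", {
  man <- make_manifest()
  pairs <- unique(man[, c("animal_id", "ics")])
  all_lv <- eligibility_labels(pairs$animal_id, pairs$ics, rep("lv", nrow(pairs)))
  expect_identical(select_eligible(man, all_lv), man)
  none <- eligibility_labels(pairs$animal_id, pairs$ics, rep("apex", nrow(pairs)))
  expect_equal(nrow(select_eligible(man, none)), 0)
  # 2 of 5 spaces eligible per animal: 2 * 7 * 3 * 12 images
  two <- eligibility_labels(pairs$animal_id, pairs$ics,
                            ifelse(pairs$ics %in% c(5, 6), "lv;apex", "aortic_root"))
  expect_equal(nrow(select_eligible(man, two)), 2 * 7 * 3 * 12)
  # unlabelled pair is an error naming it
  short <- eligibility_labels("a01", 4, "lv")
  expect_error(select_eligible(man, short), "a01 5|a02 4")
})

test_that("screening draws to quota, excludes flagged images, errors when exhausted", {
  man <- make_manifest()
  scr <- screen_and_sample(man, 50, seed = 1)
  expect_equal(scr$n_screened, 150)
  expect_equal(nrow(scr$excluded), 0)
  expect_equal(as.integer(table(scr$retained$state)), c(50, 50, 50))
  all_flagged <- make_manifest(flag = TRUE)
  expect_error(screen_and_sample(all_flagged, 50, seed = 1),
               "insufficient eligible images")
  one_state_short <- make_manifest(n_animals = 1, states = "arrest")
  expect_error(screen_and_sample(one_state_short, 61, seed = 1), "arrest")
})

test_that("the packaged screening fixture reproduces the screening log", {
  fx <- example_screening_manifest()
  expect_equal(nrow(fx$manifest), 828)
  expect_equal(sum(fx$manifest$rib_shadow_flag), 10)
  scr <- screen_and_sample(fx$manifest, 50, fx$seed)
  expect_equal(nrow(scr$retained), 150)
  expect_equal(nrow(scr$excluded), 10)
  expect_equal(scr$n_screened, 160)
  expect_equal(as.integer(table(scr$retained$state)), c(50, 50, 50))
})

test_that("blinding assigns opaque codes, shuffles deterministically, round-trips", {
  man <- make_manifest(n_animals = 2)
  scr <- screen_and_sample(man, 20, seed = 3)
  sm1 <- blind_and_shuffle(scr$retained, seed = 9)
  sm2 <- blind_and_shuffle(scr$retained, seed = 9)
  expect_identical(sm1, sm2)
  sm3 <- blind_and_shuffle(scr$retained, seed = 10)
  expect_false(identical(sm1$blinding_key$source_path, sm3$blinding_key$source_path))
  # bijection: every code decodes to a unique source image
  expect_equal(anyDuplicated(sm1$blinding_key$source_path), 0)
  k <- decode_image(sm1, "IMG-0005")
  expect_equal(nrow(k), 1)
  expect_true(k$source_path %in% scr$retained$image_path)
  expect_error(decode_image(sm1, "IMG-9999"), "IMG-9999")
  # reviewer-facing entries leak no state metadata
  packet_text <- c(sm1$entries$image_code, sm1$entries$image_path)
  expect_false(any(grepl("pre|arrest|late", packet_text)))
  dup <- scr$retained[c(1, 1, 2), ]
  expect_error(blind_and_shuffle(dup, 1), "duplicate")
})

test_that("score_study produces one record per (image, reviewer) and flags gaps", {
  man <- make_manifest(n_animals = 1, states = "arrest")
  scr <- screen_and_sample(man, 2, seed = 2)
  sm <- blind_and_shuffle(scr$retained, seed = 2)
  codes <- sm$entries$image_code
  blob <- crop_to_scan_area(random_blob(c(48, 64), c(22, 32), 8, seed = 1))
  dev <- setNames(lapply(codes, function(x) blob), codes)
  revs <- list(r1 = dev, r2 = dev)
  recs <- score_study(sm, dev, revs)
  expect_equal(nrow(recs), 2 * 2)
  expect_true(all(recs$sdi == 1))
  expect_error(score_study(sm, dev, list(r1 = dev[-1])),
               paste0("missing mask.*", codes[1], ".*r1"))
  expect_error(score_study(sm, dev[-2], revs),
               paste0("missing device mask.*", codes[2]))
})

test_that("aggregation reproduces hand-computed cells and the pooled-row contract", {
  key <- data.frame(image_code = sprintf("IMG-%04d", 1:4),
                    animal_id = "a01", state = rep(c("arrest", "late_arrest"), each = 2),
                    ics = 4L, scan_index = 1L, plane_index = 1:4,
                    source_path = letters[1:4], stringsAsFactors = FALSE)
  recs <- expand.grid(image_code = key$image_code, reviewer_id = c("r1", "r2"),
                      stringsAsFactors = FALSE)
  recs$sdi <- 1
  s <- aggregate_concordance(recs, key)
  expect_true(all(s$mean_sdi == 1) && all(s$sd_sdi == 0))
  # one reviewer, one state, SDIs {0, 1}: mean 0.5, sd ~ 0.7071
  recs01 <- data.frame(image_code = key$image_code[1:2], reviewer_id = "r1",
                       sdi = c(0, 1), stringsAsFactors = FALSE)
  s01 <- aggregate_concordance(recs01, key)
  cell <- s01[s01$reviewer_id == "r1" & s01$state == "arrest", ]
  expect_equal(cell$mean_sdi, 0.5)
  expect_equal(cell$sd_sdi, sqrt(0.5), tolerance = 1e-12)
  # randomized records against direct recomputation
  set.seed(5)
  recs_rand <- expand.grid(image_code = key$image_code,
                           reviewer_id = c("r1", "r2", "r3"),
                           stringsAsFactors = FALSE)
  recs_rand$sdi <- round(runif(nrow(recs_rand)), 6)
  sr <- aggregate_concordance(recs_rand, key)
  st_of <- key$state[match(recs_rand$image_code, key$image_code)]
  for (i in which(sr$reviewer_id != "pooled")) {
    x <- recs_rand$sdi[recs_rand$reviewer_id == sr$reviewer_id[i] &
                         st_of == sr$state[i]]
    expect_equal(sr$mean_sdi[i], sum(x) / length(x), tolerance = 1e-14)
    expect_equal(sr$sd_sdi[i], sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
                 tolerance = 1e-12)
  }
  # pooled mean per state equals the unweighted mean of reviewer means
  for (s_ in unique(sr$state)) {
    rev_means <- sr$mean_sdi[sr$state == s_ & sr$reviewer_id != "pooled"]
    expect_equal(sr$mean_sdi[sr$state == s_ & sr$reviewer_id == "pooled"],
                 mean(rev_means), tolerance = 1e-14)
  }
  # a (reviewer, state) cell with no images is an error
  expect_error(aggregate_concordance(recs01[1, ], key[3, ]), "no records|not in")
})

test_that("a small end-to-end run completes with the expected record count", {
  rc <- run_config(phantom = phantom_config(128, 96), quota_per_state = 5L,
                   n_animals = 1L, master_seed = 3L)
  res <- run_study(rc)
  expect_equal(nrow(res$records), 5 * 3 * 3)  # quota x states x reviewers
  expect_true(all(res$records$sdi >= 0 & res$records$sdi <= 1))
  expect_equal(sort(unique(res$summary$reviewer_id)), c("pooled", "r1", "r2", "r3"))
  # per-reviewer cells carry exactly the quota
  per_rev <- res$summary[res$summary$reviewer_id != "pooled", ]
  expect_true(all(per_rev$n_images == 5))
})

test_that("scaling one reviewer's jitter up drags that reviewer's mean SDI down", {
  base <- phantom_config(128, 96)
  revs <- base$reviewer_jitter_sd
  revs["r2"] <- revs["r2"] * 4
  rc <- run_config(phantom = base, reviewers = revs, quota_per_state = 5L,
                   n_animals = 1L, master_seed = 21L)
  res <- run_study(rc)
  means <- tapply(res$records$sdi, res$records$reviewer_id, mean)
  expect_lt(means["r2"], means["r1"])
  expect_lt(means["r2"], means["r3"])
})
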