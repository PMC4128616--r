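test_that("simulation is deterministic given the config seed", {
  cfg <- sim_config(random_template(300, seed = 21), seed = 21)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$record, b$record)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_trace(sim_config(random_template(300, seed = 21), seed = 22))
  expect_false(identical(a$record$channels, c2$record$channels))
})

test_that("single-template truth has no divergence and calls match", {
  t1 <- random_template(400, seed = 31)
  out <- simulate_trace(sim_config(t1, seed = 31))
  expect_false(out$truth$is_mixture)
  expect_length(out$truth$divergent_positions, 0L)
  expect_identical(out$truth$consensus_length, 400L)
  # past the 5' ramp the caller recovers the template essentially verbatim
  calls <- strsplit(out$record$basecalls, "")[[1]]
  tpl <- strsplit(t1, "")[[1]]
  post_ramp <- 30:400
  expect_gt(mean(calls[post_ramp] == tpl[post_ramp]), 0.995)
})

test_that("50:50 mixtures depress quality at exactly the divergent sites", {
  t1 <- random_template(600, seed = 41)
  t2 <- divergent_template(t1, 0.1, seed = 41)
  expect_identical(
    sum(strsplit(t1, "")[[1]] != strsplit(t2, "")[[1]]), 60L)
  out <- simulate_trace(sim_config(c(t1, t2), proportions = c(0.5, 0.5),
                                   seed = 41))
  div <- out$truth$divergent_positions
  expect_identical(length(div), 60L)
  expect_true(all(out$record$qualities[div + 1] < 20))
  feats <- measure_features(out$record)
  ratio <- feats$secondary / feats$primary
  expect_true(all(ratio[div + 1] >= 0.8 & ratio[div + 1] <= 1.0))
})

test_that("clean traces have near-zero uncalled/called ratio and spacing deviation", {
  out <- simulate_trace(sim_config(random_template(500, seed = 51),
                                   head_ramp_len = 0, seed = 51))
  feats <- measure_features(out$record)
  expect_true(all(feats$secondary / feats$primary < 0.1))
  expect_true(all(feats$resolution >= 0 & feats$resolution <= 1))

  flat <- make_flat_record(rep(40L, 50))  # exactly uniform peak spacing
  devs <- measure_features(flat)$spacing_dev
  expect_true(all(devs == 0))
})

test_that("quality calibration holds at default noise", {
  med <- integer(5); frac <- double(5)
  for (s in 1:5) {
    out <- simulate_trace(sim_config(random_template(600, seed = 60 + s),
                                     seed = 60 + s))
    med[[s]] <- median(out$record$qualities)
    tr <- trim_read(to_read(out$record))
    frac[[s]] <- classify_purity(tr)$fraction_subthreshold
  }
  expect_true(all(med >= 30))
  expect_true(all(frac < 0.01))
})

test_that("one-base length polymorphism scrambles downstream positions", {
  t1 <- random_template(600, seed = 71)
  out <- simulate_trace(sim_config(c(t1, t1), proportions = c(0.5, 0.5),
                                   indel_offsets = c(0L, 1L), seed = 71))
  # offset templates disagree wherever adjacent bases differ: ~3/4 of sites
  frac_div <- length(out$truth$divergent_positions) /
    out$truth$consensus_length
  expect_gt(frac_div, 0.6)
  # the scrambled read has no clean 5' window left
  tr <- trim_read(to_read(out$record))
  expect_identical(tr$status, "failed_head")
  expect_identical(classify_purity(tr)$classification, "indeterminate")
})

test_that("generate_dataset writes reproducible files plus a truth table", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfgs <- list(
    sim_config(random_template(200, seed = 81), seed = 81, id = "p1"),
    sim_config(c(random_template(200, seed = 82),
                 divergent_template(random_template(200, seed = 82),
                                    0.1, seed = 82)),
               proportions = c(0.5, 0.5), seed = 82, id = "m1"))
  truth <- generate_dataset(cfgs, dir1)
  expect_identical(nrow(truth), 2L)
  expect_identical(truth$is_mixture, c(FALSE, TRUE))
  expect_true(all(file.exists(file.path(dir1, truth$file))))
  expect_true(file.exists(file.path(dir1, "truth.tsv")))

  generate_dataset(cfgs, dir2)
  for (f in truth$file) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }

  empty <- generate_dataset(list(), withr::local_tempdir())
  expect_identical(nrow(empty), 0L)
})

test_that("sim_config rejects invalid mixtures", {
  t1 <- random_template(50, seed = 1)
  expect_error(sim_config(t1, proportions = c(0.5, 0.5)), "proportions")
  expect_error(sim_config(c(t1, t1), proportions = c(0.6, 0.6)),
               "summing to 1")
  expect_error(sim_config(t1, noise_sd = 0), "> 0")
  expect_error(sim_config(t1, indel_offsets = -1L), "non-negative")
  expect_error(simulate_trace(sim_config(t1, indel_offsets = 55L)),
               "shorter")
})
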