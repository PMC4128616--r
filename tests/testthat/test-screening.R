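test_that("sub-QV20 fraction counts strictly below the threshold", {
  expect_identical(subqv_fraction(c(rep(30, 99), 10)),
                   list(count = 1L, fraction = 0.01))
  expect_identical(subqv_fraction(rep(40, 50)),
                   list(count = 0L, fraction = 0))
  # calls of exactly 20 are not counted
  expect_identical(subqv_fraction(c(20, 20, 40, 19))$count, 1L)
  expect_error(subqv_fraction(integer()), "non-empty")
})

test_that("classification applies the strict one-percent rule", {
  p <- trim_params()
  # Table-style worked value: 47 weak calls in 5000 retained bases = 0.94%,
  # the largest sub-QV20 percentage still classified unialgal
  q <- c(rep(10, 25), rep(40, 5000))
  q[25 + 30 + 20 * (0:46) + 1] <- 10
  tr <- trim_read(sanger_read(strrep("A", length(q)), q, id = "t1"), p)
  expect_identical(tr$end - tr$start, 5000L)
  pr <- classify_purity(tr)
  expect_identical(pr$percent_subthreshold, 0.94)
  expect_identical(pr$classification, "unialgal")

  # 1.0% exactly is mixed (strict inequality)
  q2 <- c(rep(10, 25), rep(40, 1000))
  q2[25 + 30 + 15 * (0:9) + 1] <- 10
  pr2 <- classify_purity(trim_read(sanger_read(strrep("A", 1025), q2), p))
  expect_identical(pr2$retained_length, 1000L)
  expect_identical(pr2$n_subthreshold, 10L)
  expect_identical(pr2$classification, "mixed")

  pr3 <- classify_purity(trim_read(sanger_read(strrep("A", 600),
                                               rep(40L, 600)), p))
  expect_identical(pr3$classification, "unialgal")
  expect_identical(pr3$percent_subthreshold, 0)

  ind <- classify_purity(trim_read(sanger_read(strrep("A", 100),
                                               rep(5L, 100)), p))
  expect_identical(ind$classification, "indeterminate")
})

test_that("the purity statistic ignores the arrangement of weak calls", {
  p <- trim_params()
  q <- c(rep(10, 25), rep(40, 600))
  q[25 + c(10, 60, 110, 160) + 1] <- 8
  tr <- trim_read(sanger_read(strrep("A", 625), q, id = "perm"), p)
  base <- classify_purity(tr)
  set.seed(3)
  for (i in 1:10) {
    tr2 <- tr
    tr2$read$qualities <- sample(tr$read$qualities)
    pr <- classify_purity(tr2)
    expect_identical(pr$fraction_subthreshold, base$fraction_subthreshold)
    expect_identical(pr$classification, base$classification)
  }
})

test_that("screen_batch reports pure and mixed simulated traces per truth", {
  dir <- withr::local_tempdir()
  truth <- make_fixture_batch(dir)
  report <- screen_batch(file.path(dir, truth$file))
  expect_identical(nrow(report), 5L)
  expect_identical(report$classification[!truth$is_mixture],
                   rep("unialgal", 3))
  expect_identical(report$classification[truth$is_mixture],
                   rep("mixed", 2))
  expect_true(all(report$retained_length >= 350))
  g <- glance(report)
  expect_identical(c(g$n_unialgal, g$n_mixed), c(3L, 2L))
})

test_that("screen_batch isolates per-file failures and handles empty input", {
  empty <- screen_batch(character())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("id", "classification", "reason") %in% names(empty)))

  dir <- withr::local_tempdir()
  ok <- file.path(dir, "ok.ab1")
  write_abif(simulate_trace(sim_config(random_template(600, seed = 9),
                                       seed = 9))$record, ok)
  corrupt <- file.path(dir, "bad.ab1")
  writeBin(charToRaw("FAKEFILE"), corrupt)
  report <- screen_batch(c(ok, corrupt, file.path(dir, "missing.ab1")))
  expect_identical(report$classification,
                   c("unialgal", "indeterminate", "indeterminate"))
  expect_match(report$reason[[2]], "not an ABIF file")
  expect_identical(sum(is.na(report$reason)), 1L)

  # report writes as TSV with stable columns
  out <- file.path(dir, "report.tsv")
  write_screen_report(report, out)
  back <- utils::read.delim(out)
  expect_identical(names(back)[1:4], c("id", "status", "start", "end"))
  expect_identical(nrow(back), 3L)
})
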