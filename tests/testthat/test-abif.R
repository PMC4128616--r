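roundtrip_fields <- c("channels", "channel_order", "peak_positions",
                      "basecalls", "qualities", "sample")

test_that("ABIF files round-trip on all declared fields", {
  dir <- withr::local_tempdir()
  rec <- simulate_trace(sim_config(random_template(120, seed = 4),
                                   seed = 4))$record
  f <- file.path(dir, "sim.ab1")
  write_abif(rec, f)
  back <- read_abif(f)
  expect_identical(back[roundtrip_fields], rec[roundtrip_fields])
  expect_identical(back$instrument, rec$instrument)

  # degenerate record: zero bases, zero scans
  empty <- trace_record(list(A = numeric(), C = numeric(),
                             G = numeric(), T = numeric()),
                        integer(), "", integer())
  f2 <- file.path(dir, "empty.ab1")
  write_abif(empty, f2)
  back2 <- read_abif(f2)
  expect_identical(nchar(back2$basecalls), 0L)
  expect_identical(length(back2$channels$A), 0L)

  # IUPAC ambiguity calls and non-standard channel order survive
  mixed <- make_flat_record(c(40L, 12L, 7L), calls = c("N", "Y", "A"))
  mixed$channel_order <- "ACGT"
  f3 <- file.path(dir, "iupac.ab1")
  write_abif(mixed, f3)
  expect_identical(read_abif(f3)$basecalls, "NYA")
  expect_identical(read_abif(f3)$channel_order, "ACGT")
})

test_that("ABIF round-trip holds on randomised trace records", {
  dir <- withr::local_tempdir()
  for (s in 1:30) {
    rec <- random_trace_record(s)
    f <- file.path(dir, sprintf("r%d.ab1", s))
    write_abif(rec, f)
    expect_identical(read_abif(f)[roundtrip_fields], rec[roundtrip_fields])
  }
})

test_that("invalid records are rejected before writing", {
  expect_error(
    trace_record(list(A = 1:4, C = 1:4, G = 1:4, T = 1:4),
                 c(0L, 2L), "AC", c(40L, 94L)),
    "\\[0, 93\\]")
  rec <- make_flat_record(c(40L, 40L))
  rec$channels$A[1] <- 0.5
  f <- withr::local_tempfile(fileext = ".ab1")
  expect_error(write_abif(rec, f), "integers")
  expect_false(file.exists(f))
})

test_that("malformed files fail with diagnostic errors", {
  dir <- withr::local_tempdir()
  fake <- file.path(dir, "fake.ab1")
  writeBin(c(charToRaw("FAKE"), raw(200)), fake)
  expect_error(read_abif(fake), "not an ABIF file")
  expect_error(read_abif(file.path(dir, "nope.ab1")), "file not found")

  # byte surgery: shrink PCON to 9 elements against 10 basecalls
  rec <- make_flat_record(rep(40L, 10))
  f <- file.path(dir, "surgery.ab1")
  write_abif(rec, f)
  r <- readBin(f, raw(), file.size(f))
  hits <- which(r == charToRaw("P"))
  pcon_at <- hits[vapply(hits, function(i) {
    i + 3 <= length(r) && rawToChar(r[i:(i + 3)]) == "PCON"
  }, logical(1))]
  off <- pcon_at[[length(pcon_at)]]  # directory copy is the last occurrence
  r[(off + 12):(off + 15)] <- writeBin(9L, raw(), size = 4, endian = "big")
  writeBin(r, f)
  expect_error(read_abif(f), "corrupt trace")

  # byte surgery: rename the PLOC tag away entirely
  write_abif(rec, f)
  r <- readBin(f, raw(), file.size(f))
  hits <- which(r == charToRaw("P"))
  ploc_at <- hits[vapply(hits, function(i) {
    i + 3 <= length(r) && rawToChar(r[i:(i + 3)]) == "PLOC"
  }, logical(1))]
  off <- ploc_at[[length(ploc_at)]]
  r[off:(off + 3)] <- charToRaw("XXXX")
  writeBin(r, f)
  expect_error(read_abif(f), "incomplete trace")
})

test_that("to_read carries calls, qualities and sample name", {
  rec <- make_flat_record(c(40L, 30L, 12L), calls = c("A", "N", "Y"),
                          sample = "cult-1")
  rd <- to_read(rec)
  expect_identical(rd$sequence, "ANY")
  expect_identical(rd$qualities, c(40L, 30L, 12L))
  expect_identical(rd$id, "cult-1")
  e <- to_read(trace_record(list(A = numeric(), C = numeric(),
                                 G = numeric(), T = numeric()),
                            integer(), "", integer()))
  expect_identical(length(e), 0L)
})
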