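test_that("write -> read round-trips a simulated trial", {
  tr <- get_trial("DJ15")
  dir <- withr::local_tempdir()
  write_trial(tr, file.path(dir, "t1"))
  back <- read_trial(file.path(dir, "t1"))
  expect_identical(back$jump_type, tr$jump_type)
  expect_identical(back$drop_height, tr$drop_height)
  expect_equal(back$subject[1:5], tr$subject[1:5])
  expect_equal(back$force$values, tr$force$values)
  expect_equal(back$kinematics$values, tr$kinematics$values)
  expect_equal(back$truth$torque$values, tr$truth$torque$values)
  expect_equal(back$truth$com$values, tr$truth$com$values)
  expect_identical(back$truth$contact, tr$truth$contact)
  expect_length(validate_trial(back), 0)
})

test_that("invalid trials are rejected with named violations", {
  tr <- get_trial("DJ15")
  dir <- withr::local_tempdir()

  nan <- tr
  nan$force$values[10, "fz_l"] <- NaN
  expect_error(write_trial(nan, file.path(dir, "bad")), class = "jw_format_error")
  expect_match(validate_trial(nan), "non-finite", all = FALSE)

  empty <- tr
  empty$force <- timeseries(matrix(0, 1, 6,
                                   dimnames = list(NULL, colnames(tr$force$values))),
                            rate = 1000)
  expect_error(write_trial(empty, file.path(dir, "bad")), class = "jw_format_error")

  # rate mismatch reported, not silently accepted
  odd <- tr
  odd$force$rate <- 500
  odd$force$t <- (seq_len(nrow(odd$force$values)) - 1) / 500
  expect_match(validate_trial(odd), "rate", all = FALSE)
})

test_that("corrupted files yield format errors naming the problem", {
  tr <- get_trial("DJ15")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t2")
  write_trial(tr, p)

  # shuffled time column
  f <- utils::read.delim(file.path(p, "force.tsv"))
  f$t <- sample(f$t)
  utils::write.table(f, file.path(p, "force.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_trial(p), class = "jw_format_error")

  # truncated force table
  write_trial(tr, p)
  ln <- readLines(file.path(p, "force.tsv"))
  writeLines(ln[1:2], file.path(p, "force.tsv"))
  err <- tryCatch(read_trial(p), error = function(e) e)
  expect_s3_class(err, "jw_format_error")
  expect_match(conditionMessage(err), "row")

  # missing channel
  write_trial(tr, p)
  f <- utils::read.delim(file.path(p, "kinematics.tsv"))
  f$hip_l <- NULL
  utils::write.table(f, file.path(p, "kinematics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  err <- tryCatch(read_trial(p), error = function(e) e)
  expect_s3_class(err, "jw_format_error")
  expect_match(conditionMessage(err), "hip_l")
})
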