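make_trap_file <- function(path, n_sites = 3, n_days = 10, daily = TRUE,
                           coords = NULL, dup = FALSE, bad_coord = FALSE,
                           ragged = FALSE) {
  ids <- sprintf("T%02d", seq_len(n_sites))
  if (dup) ids[2] <- ids[1]
  if (is.null(coords))
    coords <- cbind(x = 700000 + seq_len(n_sites) * 3000,
                    y = 5200000 + seq_len(n_sites) * 2000)
  flags <- matrix(1L, n_sites, n_days)
  pre <- if (daily) "d" else "o"
  header <- paste(c("site", "x", "y", paste0(pre, seq_len(n_days))), collapse = ",")
  rows <- vapply(seq_len(n_sites), function(i) {
    xi <- if (bad_coord && i == 2) "not_a_number" else format(coords[i, 1])
    paste(c(ids[i], xi, format(coords[i, 2]), flags[i, ]), collapse = ",")
  }, character(1))
  if (ragged) rows[2] <- paste(rows[2], "1", sep = ",")
  writeLines(c(header, rows), path)
  path
}

test_that("daily trap files collapse to occasions by the ceiling rule", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f, n_sites = 3, n_days = 10)
  tr <- read_traps(f, occasion_length = 5)
  expect_equal(dim(tr$activity), c(3, 2))
  expect_true(all(tr$activity == 1L))

  # a 63-day deployment yields ceiling(63/5) = 13 occasions, the last short
  f2 <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f2, n_sites = 44, n_days = 63)
  tr2 <- read_traps(f2, occasion_length = 5)
  expect_equal(ncol(tr2$activity), 13)
  expect_equal(nrow(tr2$activity), 44)
})

test_that("trap file validation names the offending row/column", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f, dup = TRUE)
  expect_error(read_traps(f), class = "scrdens_duplicate_site")

  f2 <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f2, bad_coord = TRUE)
  err <- expect_error(read_traps(f2), class = "scrdens_bad_coordinate")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "'x'")

  f3 <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f3, ragged = TRUE)
  err <- expect_error(read_traps(f3), class = "scrdens_ragged_row")
  expect_match(conditionMessage(err), "row 3")  # header is row 1

  f4 <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f4, coords = cbind(x = c(6.1, 6.2, 6.3), y = c(46.5, 46.6, 46.7)))
  expect_error(read_traps(f4), class = "scrdens_geographic_coords")
})

test_that("day indices map to occasions and short trailing occasions survive", {
  expect_equal(day_to_occasion(c(1, 5, 6, 11, 60), 5), c(1, 1, 2, 3, 12))
  act <- matrix(1L, 2, 63)
  col <- collapse_occasions(array(0L, c(0, 2, 63)), act, 5)
  expect_equal(ncol(col$activity), 13)
  # last occasion covers days 61..63 only
  act2 <- matrix(0L, 1, 63); act2[1, 61:63] <- 1L
  col2 <- collapse_occasions(array(0L, c(0, 1, 63)), act2, 5)
  expect_equal(which(col2$activity[1, ] == 1L), 13)
  expect_error(collapse_occasions(array(0L, c(0, 1, 5)), matrix(1L, 1, 5), 0),
               class = "scrdens_validation_error")
})

test_that("collapsing is idempotent and never invents detections on inactive cells", {
  set.seed(11)
  J <- 4; D <- 17; n <- 3
  act <- matrix(rbinom(J * D, 1, 0.8), J, D)
  act[rowSums(act) == 0, 1] <- 1L
  y <- array(0L, c(n, J, D))
  for (i in 1:n) y[i, , ] <- matrix(rbinom(J * D, 1, 0.2), J, D) * act
  col <- collapse_occasions(y, act, 5)
  expect_true(all(col$y <= aperm(array(col$activity, c(J, ncol(col$activity), n)),
                                 c(3, 1, 2))))
  # collapsing again at occasion granularity (length 1) changes nothing
  again <- collapse_occasions(col$y, col$activity, 1)
  expect_identical(again$y, col$y)
  expect_identical(again$activity, col$activity)
})

test_that("repeat photographs within an occasion collapse to one detection", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f, n_sites = 3, n_days = 10)
  traps <- read_traps(f)
  e <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,day,site,sex",
               "s1,A,2,T01,F", "s1,A,3,T01,F", "s1,A,4,T01,F",
               "s1,B,7,T02,U"), e)
  enc <- read_encounters(e, traps)
  expect_equal(dim(enc$y)[1], 2)
  expect_equal(sum(enc$y), 2)
  expect_equal(enc$y["A", "T01", 1], 1L)
  expect_equal(enc$sex, c("F", "U"))
})

test_that("encounter validation: empty files, unknown sites, inactive cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f, n_sites = 2, n_days = 10)
  traps <- read_traps(f)

  e0 <- withr::local_tempfile(fileext = ".csv")
  writeLines("session,individual,day,site,sex", e0)
  enc0 <- read_encounters(e0, traps)
  expect_equal(dim(enc0$y)[1], 0)

  e1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,day,site", "s1,A,1,NOPE"), e1)
  expect_error(read_encounters(e1, traps), class = "scrdens_unknown_site")

  # site T02 inactive on days 6-10 (occasion 2)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c("site,x,y", paste0("d", 1:10)), collapse = ","),
               paste(c("T01,700000,5200000", rep(1, 10)), collapse = ","),
               paste(c("T02,705000,5204000", rep(1, 5), rep(0, 5)), collapse = ",")),
             f2)
  traps2 <- read_traps(f2)
  e2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,day,site", "s1,A,8,T02"), e2)
  expect_error(read_encounters(e2, traps2), class = "scrdens_inactive_detection")
  expect_warning(enc2 <- read_encounters(e2, traps2, on_inactive = "drop"),
                 "dropping")
  expect_equal(dim(enc2$y)[1], 0)
})

test_that("write/read round-trips reproduce arrays exactly", {
  s <- small_sim_session(seed = 3)
  traps <- s$sim$traps; enc <- s$sim$encounters
  tf <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  write_traps(traps, tf)
  write_encounters(enc, ef)
  traps2 <- read_traps(tf)
  enc2 <- read_encounters(ef, traps2, session = enc$session_id)
  expect_identical(traps2$site_id, traps$site_id)
  expect_identical(traps2$x, traps$x)
  expect_identical(traps2$y, traps$y)
  expect_identical(traps2$activity, traps$activity)
  expect_identical(sort(enc2$individuals), sort(enc$individuals))
  expect_identical(enc2$y[enc$individuals, , ], enc$y)
  expect_identical(enc2$sex[match(enc$individuals, enc2$individuals)], enc$sex)
})

test_that("detection events are invariant to record order and duplication", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_trap_file(f, n_sites = 3, n_days = 10)
  traps <- read_traps(f)
  rows <- c("s1,A,2,T01", "s1,B,7,T02", "s1,A,9,T03", "s1,A,2,T01")
  e1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,day,site", rows), e1)
  e2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session,individual,day,site", rev(rows), rows), e2)
  enc1 <- read_encounters(e1, traps)
  enc2 <- read_encounters(e2, traps)
  ord <- match(enc1$individuals, enc2$individuals)
  expect_identical(enc2$y[ord, , ], enc1$y)
  expect_equal(sum(enc1$y), 3)
})
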