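test_that("sample-and-hold expansion follows the placeholder definition", {
  s <- ts_stream(c(0, 1e9), c(10, 20), native_rate_hz = 1)
  tab <- synchronize(list(s), sync_config(4, t_start_ns = 0, t_end_ns = 2e9))
  key <- names(tab$columns)[1]
  expect_equal(tab$columns[[key]], c(10, 10, 10, 10, 20, 20, 20, 20))
  expect_equal(tab$freshness[[key]],
               c("fresh", "held", "held", "held",
                 "fresh", "held", "held", "held"))
})

test_that("a stream already on the master grid passes through fresh", {
  ts <- seq(0, 1e9, by = 0.25e9)
  s <- ts_stream(ts, 1:5, native_rate_hz = 4)
  tab <- synchronize(list(s), sync_config(4))
  key <- names(tab$columns)[1]
  expect_equal(tab$columns[[key]], as.numeric(1:5))
  expect_true(all(tab$freshness[[key]] == "fresh"))
})

test_that("mixed-rate fusion yields complete rows at the master rate", {
  set.seed(21)
  slow <- random_stream(0.5, 10, id = "moxy", metric = "sto2", jitter = 0)
  fast <- random_stream(200, 10, id = "biopac", metric = "ecg", jitter = 0)
  tab <- synchronize(list(slow, fast),
                     sync_config(200, t_start_ns = 0, t_end_ns = 10e9))
  expect_equal(length(tab$tick_times_ns), 2000)
  for (key in names(tab$columns))
    expect_true(all(tab$freshness[[key]] %in% c("fresh", "held")))
  # master tick spacing exact, no drift
  expect_true(all(diff(tab$tick_times_ns) == 5e6))
})

test_that("invalid samples are skipped and empty streams warn", {
  s <- ts_stream(c(0, 1e9, 2e9), c(1, 99, 3),
                 valid = c(TRUE, FALSE, TRUE), native_rate_hz = 1)
  tab <- synchronize(list(s), sync_config(1, t_start_ns = 0, t_end_ns = 3e9))
  expect_equal(tab$columns[[1]], c(1, 1, 3))
  empty <- ts_stream(c(0, 1e9), c(1, 2), valid = c(FALSE, FALSE),
                     device_id = "dead")
  expect_warning(
    tab2 <- synchronize(list(s, empty), sync_config(1, t_start_ns = 0,
                                                    t_end_ns = 3e9)),
    "no valid samples")
  expect_true(all(tab2$freshness[["dead.metric"]] == "missing"))
  expect_error(ts_stream(c(1e9, 1e9), c(1, 2)), "strictly increasing")
})

test_that("synchronize matches a brute-force per-tick scan on random sessions", {
  set.seed(42)
  rates <- c(0.5, 1, 38, 200)
  for (rep in 1:50) {
    n_streams <- sample(1:5, 1)
    dur <- runif(1, 2, 10)
    streams <- lapply(seq_len(n_streams), function(i)
      random_stream(sample(rates, 1), dur, id = paste0("d", i)))
    t_end <- round(dur * 1e9)
    tab <- synchronize(streams, sync_config(200, t_start_ns = 0,
                                            t_end_ns = t_end))
    oracle <- brute_force_sync(streams, 200, 0, t_end)
    expect_identical(tab$tick_times_ns, oracle$ticks)
    for (key in names(tab$columns)) {
      expect_identical(tab$columns[[key]], oracle$cols[[key]]$values)
      expect_identical(tab$freshness[[key]], oracle$cols[[key]]$freshness)
      # every row complete: fresh, held, or explicitly missing
      expect_true(all(tab$freshness[[key]] %in%
                        c("fresh", "held", "missing")))
    }
  }
})

test_that("deduplicate_held inverts sample-and-hold exactly", {
  s <- ts_stream(c(0, 1e9), c(10, 20), native_rate_hz = 1)
  tab <- synchronize(list(s), sync_config(4, t_start_ns = 0, t_end_ns = 2e9))
  d <- deduplicate_held(tab, names(tab$columns)[1])
  expect_equal(d$values, c(10, 20))

  # all-held column from a single sample
  s1 <- ts_stream(0, 7, device_id = "one")
  tab1 <- synchronize(list(s1), sync_config(4, t_start_ns = 0,
                                            t_end_ns = 1e9))
  d1 <- deduplicate_held(tab1, "one.metric")
  expect_equal(d1$values, 7)

  set.seed(7)
  for (rep in 1:50) {
    # native rates below the master tick rate: each sample gets its own
    # tick, so inversion is exact (at the master rate itself, sampling
    # jitter can put two samples in one tick and only the later survives)
    rate <- sample(c(0.5, 1, 38, 200), 1)
    s <- random_stream(rate, runif(1, 2, 10),
                       jitter = if (rate >= 200) 0 else 0.1)
    tab <- synchronize(list(s), sync_config(200))
    d <- deduplicate_held(tab, names(tab$columns)[1])
    expect_equal(stream_length(d), stream_length(s))
    expect_identical(d$values, s$values)
    # held cells equal the nearest earlier fresh cell (conservation)
    col <- tab$columns[[1]]
    fl <- tab$freshness[[1]]
    held <- which(fl == "held")
    if (length(held)) {
      prev_fresh <- vapply(held, function(j)
        max(which(fl[1:j] == "fresh")), integer(1))
      expect_identical(col[held], col[prev_fresh])
    }
  }
})

test_that("synchronize is idempotent through deduplication", {
  set.seed(9)
  s <- random_stream(1, 10, id = "polar", metric = "hr")
  cfg <- sync_config(50, t_start_ns = 0, t_end_ns = 10e9)
  tab1 <- synchronize(list(s), cfg)
  rec <- deduplicate_held(tab1, "polar.hr")
  tab2 <- synchronize(list(rec), cfg)
  expect_identical(tab1$columns[[1]], tab2$columns[[1]])
  expect_identical(tab1$freshness[[1]], tab2$freshness[[1]])
})

test_that("session files round-trip losslessly", {
  set.seed(13)
  slow <- random_stream(0.5, 12, id = "moxy", metric = "sto2")
  fast <- random_stream(38, 12, id = "nps", metric = "ppg")
  tl <- flat_timeline(12)
  tab <- synchronize(list(slow, fast), sync_config(50), events = tl)
  f <- tempfile(fileext = ".session.json")
  on.exit(unlink(f))
  write_session(tab, f)
  tab2 <- read_session(f)
  expect_identical(tab$tick_times_ns, tab2$tick_times_ns)
  expect_equal(length(tab2$tick_times_ns),
               length(tab2$columns[[1]]))
  for (key in names(tab$columns)) {
    expect_identical(unname(tab$columns[[key]]), unname(tab2$columns[[key]]))
    expect_identical(unname(tab$freshness[[key]]),
                     unname(tab2$freshness[[key]]))
  }
  expect_equal(tab2$events$label, tl$label)
  expect_equal(tab2$stream_meta, tab$stream_meta)

  # empty event log round-trips as empty
  tab_noev <- synchronize(list(slow), sync_config(10))
  f2 <- tempfile(); on.exit(unlink(f2), add = TRUE)
  write_session(tab_noev, f2)
  expect_null(read_session(f2)$events)

  expect_error(read_session(tempfile()), "not found")
  bad <- tempfile(); writeLines("{not json", bad)
  on.exit(unlink(bad), add = TRUE)
  expect_error(read_session(bad), "corrupt")
})
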