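# Event extraction from open-count traces

test_that("hand-countable trace gives one event with max 2 and dwell 3 ms", {
  st <- opening_statistics(c(0, 0, 1, 2, 1, 0), dt = 1)
  expect_equal(st$n_events, 1L)
  expect_equal(st$max_open, 2L)
  expect_equal(st$dwell_ms, 3)
})

test_that("degenerate traces give empty outputs", {
  expect_equal(opening_statistics(integer(0))$n_events, 0L)
  z <- opening_statistics(rep(0L, 100), dt = 0.5)
  expect_equal(z$n_events, 0L)
  expect_length(z$dwell_ms, 0)
})

test_that("events at trace boundaries are counted", {
  st <- opening_statistics(c(2, 1, 0, 0, 1, 1), dt = 0.5)
  expect_equal(st$n_events, 2L)
  expect_equal(st$dwell_ms, c(1, 1))
  expect_equal(st$max_open, c(2L, 1L))
})

test_that("synthetic fixture with known event structure is recovered", {
  fx <- make_fixture("n_open_events",
                     params = list(n_events = 12, dt = 0.01), seed = 4)
  st <- opening_statistics(fx$data$n_open, dt = fx$data$dt)
  expect_equal(st$n_events, fx$truth$n_events)
  expect_equal(st$dwell_ms, fx$truth$dwell_ms, tolerance = 1e-12)
  expect_equal(st$max_open, fx$truth$max_open)
  expect_equal(sum(st$max_open_hist), st$n_events)
})
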