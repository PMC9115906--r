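test_that("breath timing converts to breaths per minute", {
  expect_equal(rr_from_breath_timing(6), 100)
  expect_equal(rr_from_breath_timing(60), 10)
  expect_equal(rr_from_breath_timing(5.2), 600 / 5.2)
  expect_error(rr_from_breath_timing(0), "positive")
  expect_error(rr_from_breath_timing(-3), "positive")
})

make_rt <- function(values, start = "2014-07-28 06:00:00") {
  tibble::tibble(
    animal_id = "A1",
    timestamp = as.POSIXct(start, tz = "UTC") +
      600 * (seq_along(values) - 1),
    value = values)
}

test_that("rumen-temperature sanitization drops <= 35 C and logs it", {
  s <- sanitize_rt(make_rt(c(39.5, 34.9, 40.1)))
  expect_equal(s$retained$value, c(39.5, 40.1))
  expect_equal(nrow(s$rejected), 1)
  expect_match(s$rejected$reason, "le_35")

  empty <- sanitize_rt(make_rt(numeric(0)))
  expect_equal(nrow(empty$retained), 0)

  clean <- sanitize_rt(make_rt(c(39, 40, 41)))
  expect_equal(clean$retained$value, c(39, 40, 41))
  expect_equal(nrow(clean$rejected), 0)
})

test_that("optional water-event masking removes post-drinking readings", {
  rt <- make_rt(c(39.8, 37.2, 37.5, 39.6))  # dips after a big drink
  ev <- tibble::tibble(animal_id = "A1",
                       timestamp = rt$timestamp[1] + 300, litres = 10)
  off <- sanitize_rt(rt)
  expect_equal(nrow(off$retained), 4)  # default: rule not applied
  # readings fall 5, 15, 25 min after the event; a 20-min window masks
  # the two dipped readings and keeps the recovered one
  on <- sanitize_rt(rt, mask_wc_events = TRUE, wc_events = ev,
                    wc_window_min = 20)
  expect_equal(on$retained$value, c(39.8, 39.6))
  expect_true(all(on$rejected$reason == "post_wc_event"))
  # sub-threshold event does not mask
  small <- sanitize_rt(rt, mask_wc_events = TRUE,
                       wc_events = transform(ev, litres = 5))
  expect_equal(nrow(small$retained), 4)
})

test_that("bolus retransmissions collapse to one record per timestamp", {
  ts <- as.POSIXct("2014-07-28 00:00:00", tz = "UTC") + 600 * (0:11)
  base <- tibble::tibble(animal_id = "A1", timestamp = ts,
                         value = 39 + 0.01 * (0:11))
  # second transmission repeats the last 11 points plus one new reading
  tr2 <- base[2:12, ]
  tr2 <- rbind(tr2, tibble::tibble(animal_id = "A1",
                                   timestamp = ts[12] + 600, value = 39.2))
  recs <- rbind(transform(base, transmission_id = 1L),
                transform(tr2, transmission_id = 2L))
  dd <- dedupe_bolus_transmissions(recs)
  expect_equal(nrow(recs), 24)
  expect_equal(nrow(dd$unique), 13)
  expect_equal(nrow(dd$conflicts), 0)

  # disjoint transmissions: count preserved
  disj <- rbind(transform(base, transmission_id = 1L),
                transform(base, timestamp = timestamp + 7200,
                          transmission_id = 2L))
  expect_equal(nrow(dedupe_bolus_transmissions(disj)$unique), 24)
})

test_that("conflicting duplicates: latest transmission wins, logged", {
  ts <- as.POSIXct("2014-07-28 00:00:00", tz = "UTC")
  recs <- tibble::tibble(
    animal_id = "A1", timestamp = rep(ts, 3),
    value = c(39.0, 39.5, 39.3), transmission_id = c(1L, 3L, 2L))
  dd <- dedupe_bolus_transmissions(recs)
  expect_equal(dd$unique$value, 39.5)  # transmission 3 is latest
  expect_equal(nrow(dd$conflicts), 1)
  expect_equal(dd$conflicts$n_values, 3)
})

test_that("dedupe never yields two records at one animal-timestamp", {
  set.seed(5)
  ts <- as.POSIXct("2014-07-28 00:00:00", tz = "UTC") +
    600 * sample(0:50, 120, replace = TRUE)
  recs <- tibble::tibble(
    animal_id = sample(c("A1", "A2"), 120, replace = TRUE),
    timestamp = ts,
    value = round(rnorm(120, 39.5, 0.3), 2),
    transmission_id = sample(1:5, 120, replace = TRUE))
  u <- dedupe_bolus_transmissions(recs)$unique
  expect_lte(nrow(u), nrow(recs))
  expect_equal(anyDuplicated(u[, c("animal_id", "timestamp")]), 0)
})

test_that("pair offering adds 20% to the previous day's intake", {
  expect_equal(pair_offer(5), 6)
  expect_equal(pair_offer(0), 0)
  expect_equal(pair_offer(10.85), 13.02)
  expect_error(pair_offer(-1), "non-negative")
  # order-preserving: higher intake never yields a lower offer
  x <- sort(runif(20, 0, 15))
  expect_true(all(diff(pair_offer(x)) >= 0))
})

test_that("step-down offers converge gradually to the target", {
  d1 <- step_down_offer(12, 6, 3)
  d2 <- step_down_offer(d1, 6, 3)
  expect_equal(c(d1, d2), c(9, 6))
  expect_equal(step_down_offer(6, 6, 3), 6)
  expect_equal(step_down_offer(4, 6, 3), 6)  # target above prev: jump up
  # converges within ceiling(gap/drop) days
  offer <- 14; n <- 0
  while (offer > 5) { offer <- step_down_offer(offer, 5, 2.5); n <- n + 1 }
  expect_lte(n, ceiling((14 - 5) / 2.5))
})

test_that("DMI combines grain and chaff per policy", {
  led <- tibble::tibble(animal_id = "A1", day = 1,
                        offered_asfed_kg = 12, refusals_asfed_kg = 2,
                        dm_fraction = 0.9)
  expect_equal(compute_dmi(led)$dmi, 10 * 0.9 + 1.08)
  expect_equal(compute_dmi(led, chaff_policy = "prorate_refusals")$dmi,
               10 * 0.9 + 1.08 * (10 / 12))
  expect_error(compute_dmi(transform(led, refusals_asfed_kg = 13)),
               "refusals")
})

test_that("daily water consumption differences the cumulative meter", {
  ts0 <- as.POSIXct("2014-07-28 06:00:00", tz = "UTC")
  meter <- tibble::tibble(
    animal_id = "A1",
    day = c(1, 1, 2, 2, 2),
    timestamp = ts0 + c(0, 12, 24, 30, 36) * 3600,
    reading_l = c(80, 95, 100, 110, 130))
  wc <- compute_wc(meter)
  expect_equal(wc$wc, c(15, 35))  # day 2: 130 - 95
  # constant meter -> zero
  const <- transform(meter, reading_l = 50)
  expect_equal(compute_wc(const)$wc, c(0, 0))
  # decreasing meter rejected with the animal named
  bad <- transform(meter, reading_l = c(80, 95, 90, 110, 130))
  expect_error(compute_wc(bad), "A1")
})

test_that("summed daily WC telescopes to the meter span (conservation)", {
  set.seed(11)
  for (rep in 1:5) {
    inc <- runif(40, 0, 4)
    meter <- tibble::tibble(
      animal_id = "B1",
      day = rep(1:8, each = 5),
      timestamp = as.POSIXct("2014-07-28", tz = "UTC") +
        3600 * seq(6, by = 3, length.out = 40),
      reading_l = 100 + cumsum(inc))
    wc <- compute_wc(meter)
    expect_equal(sum(wc$wc),
                 meter$reading_l[40] - meter$reading_l[1])
  }
})

test_that("aggregation produces per-animal-day means with counts", {
  ts0 <- as.POSIXct("2014-07-28 06:00:00", tz = "UTC")
  recs <- tibble::tibble(
    animal_id = c("A1", "A1", "A1", "A2"),
    treatment = c("TC", "TC", "TC", "FRTN"),
    day = c(1, 1, 2, 1),
    timestamp = ts0 + c(0, 7200, 86400, 0),
    measure = c("RT", "RT", "RT", "RR"),
    value = c(39, 40, 41, 80))
  d <- aggregate_daily(recs)
  a1d1 <- d[d$animal_id == "A1" & d$day == 1, ]
  expect_equal(a1d1$mean_rt, 39.5)
  expect_equal(a1d1$n_rt, 2)
  # single record: mean equals it
  expect_equal(d$mean_rr[d$animal_id == "A2"], 80)
  # missing measure is NA, not zero
  expect_true(is.na(a1d1$mean_rr))
  # permutation invariance
  d2 <- aggregate_daily(recs[sample(nrow(recs)), ])
  expect_equal(d2, d)
})

test_that("period assignment follows the trial phases", {
  p <- assign_period(c(1, 4, 5, 11, 12, 18))
  expect_equal(as.character(p$period),
               c("PreChallenge", "PreChallenge", "Challenge", "Challenge",
                 "Recovery", "Recovery"))
  expect_equal(p$transition, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("aggregation recovers the generator's latent daily values", {
  sim <- small_sim()
  daily <- daily_from_sim(sim)
  gt <- sim$ground_truth$latent_daily
  j <- dplyr::inner_join(daily, gt, by = c("animal_id", "day"))
  # DMI and WC are recorded exactly (ledger and meter carry no noise)
  expect_equal(j$dmi.x, j$dmi.y, tolerance = 1e-8)
  expect_equal(j$wc.x, j$wc.y, tolerance = 1e-8)
  # daily bolus means track the latent daily RT mean (bolus noise
  # sd 0.05 over ~144 readings -> se ~ 0.004; sampling-grid offset small)
  expect_lt(max(abs(j$mean_rt - j$rt_mean)), 0.05)
  expect_equal(mean(j$mean_rt - j$rt_mean), 0, tolerance = 0.01)
})
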