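occ3 <- function(p = 300, u = 500, c = 100) {
  data.frame(chamber = c("center", "paired", "center", "unpaired"),
             start = c(0, c / 2, c / 2 + p, c + p),
             end = c(c / 2, c / 2 + p, c + p, c + p + u))
}

test_that("preference scores are exact chamber arithmetic", {
  s <- cpp_session(occ3(), phase = "pre")
  expect_equal(as.numeric(preference_score(s, "time")), -200)
  # entries mode counts transitions into side chambers
  expect_equal(as.numeric(preference_score(s, "entries")), 0)
  # antisymmetry: swapping chamber labels negates both modes
  occ_sw <- occ3()
  occ_sw$chamber <- c("center", "unpaired", "center", "paired")
  s_sw <- cpp_session(occ_sw, phase = "pre")
  expect_equal(as.numeric(preference_score(s_sw, "time")), 200)
  expect_equal(as.numeric(preference_score(s_sw, "entries")),
               -as.numeric(preference_score(s, "entries")))
})

test_that("malformed occupancy partitions are rejected at the first bad row", {
  occ <- occ3(); occ$start[3] <- occ$start[3] + 5
  expect_error(cpp_session(occ, "pre"), "row 3")
  occ <- occ3(); occ$chamber[2] <- "center"
  expect_error(cpp_session(occ, "pre"), "share a chamber")
  occ <- occ3(); occ$chamber <- c("paired", "unpaired", "center", "paired")
  expect_error(cpp_session(occ, "pre"), "center passage")
  occ <- occ3(); occ$chamber[1] <- "lobby"
  expect_error(cpp_session(occ, "pre"), "invalid chamber")
})

test_that("preference shift is post minus pre in a shared mode", {
  s <- cpp_session(occ3(), phase = "pre")
  expect_equal(preference_shift(preference_score(s, "time"),
                                preference_score(s, "time")), 0)
  pre <- structure(100, mode = "time")
  post <- structure(-150, mode = "time")
  expect_equal(preference_shift(pre, post), -250)
  expect_error(preference_shift(structure(1, mode = "time"),
                                structure(1, mode = "entries")),
               "modes")
})

test_that("locomotor summaries count transitions and pass beams through", {
  # 10 transitions, all dwells above the debounce: 10 entries
  ch <- rep(c("center", "paired", "center", "unpaired"), 3)[1:11]
  occ <- data.frame(chamber = ch, start = 10 * (0:10), end = 10 * (1:11))
  s <- cpp_session(occ, "pre", photobeam_count = 55)
  out <- locomotor_summary(s)
  expect_equal(out$total_entries, 10L)
  expect_equal(out$photobeam_count, 55L)
  # single interval: no entries
  one <- cpp_session(data.frame(chamber = "center", start = 0, end = 900),
                     "pre")
  expect_equal(locomotor_summary(one)$total_entries, 0L)
  # sub-debounce center traversals are not counted as center entries
  occ2 <- data.frame(chamber = c("paired", "center", "unpaired"),
                     start = c(0, 100, 100.5), end = c(100, 100.5, 200))
  s2 <- cpp_session(occ2, "pre")
  expect_equal(locomotor_summary(s2)$total_entries, 1L)
})

test_that("partition conservation holds for generated sessions", {
  for (s in 1:5) {
    sess <- generate_cpp_session(0.4, mean_dwell = 10,
                                 session_length = 900, seed = s)
    secs <- session_summary(sess)$seconds
    expect_equal(sum(secs), 900)
  }
})

test_that("biased generators produce signed scores and shifts", {
  # bias 0.25 toward paired means fewer paired entries: negative scores
  scores <- vapply(1:40, function(s)
    as.numeric(preference_score(
      generate_cpp_session(0.25, mean_dwell = 10, session_length = 3600,
                           seed = s), "entries")), 0)
  expect_gte(mean(scores < 0), 0.95)
  # symmetric bias: mean score near zero
  sym <- vapply(1:60, function(s)
    as.numeric(preference_score(
      generate_cpp_session(0.5, mean_dwell = 10, session_length = 1800,
                           seed = 100 + s), "time")), 0)
  expect_lt(abs(mean(sym)), 3 * stats::sd(sym) / sqrt(length(sym)))
  # conditioning that lowers the paired bias gives a negative mean shift
  shifts <- vapply(1:40, function(s) {
    pre <- preference_score(generate_cpp_session(
      0.5, 10, 1800, seed = 200 + s, phase = "pre"), "time")
    post <- preference_score(generate_cpp_session(
      0.3, 10, 1800, seed = 300 + s, phase = "post"), "time")
    preference_shift(pre, post)
  }, 0)
  expect_lt(mean(shifts), 0)
  expect_lt(t.test(shifts)$p.value, 0.01)
})

test_that("halving dwell times roughly doubles locomotion measures", {
  tot <- function(dwell, seed) {
    s <- generate_cpp_session(0.5, mean_dwell = dwell,
                              session_length = 3600, seed = seed)
    c(locomotor_summary(s, debounce = 0)$total_entries,
      s$photobeam_count)
  }
  a <- rowMeans(vapply(1:20, function(s) tot(20, s), c(0, 0)))
  b <- rowMeans(vapply(1:20, function(s) tot(10, s), c(0, 0)))
  expect_gt(b[1] / a[1], 1.6); expect_lt(b[1] / a[1], 2.4)
  expect_gt(b[2] / a[2], 1.6); expect_lt(b[2] / a[2], 2.4)
})

test_that("group contrasts expose lesion effects and reduce to t-tests", {
  set.seed(23)
  # identical groups: no main effect
  sh <- data.frame(animal = 1:14, group = rep(c("sham", "lesion"), 7),
                   stimulus = "licl",
                   shift = rnorm(14, -100, 30))
  out <- group_contrast(sh)
  expect_gt(out$anova$p[out$anova$term == "group"], 0.05)
  # one-factor two-level case agrees with the unpaired t-test
  tt <- t.test(shift ~ group, data = sh, var.equal = TRUE)
  expect_equal(out$anova$p[out$anova$term == "group"], tt$p.value,
               tolerance = 1e-9)
  # planted attenuation in the lesion group is detected
  df <- expand.grid(animal = 1:7, group = c("sham", "lesion"),
                    stimulus = c("licl", "siren"))
  df$shift <- rnorm(nrow(df), ifelse(df$group == "sham", -200, -80), 40)
  out2 <- group_contrast(df)
  expect_lt(out2$anova$p[out2$anova$term == "group"], 0.05)
  expect_equal(nrow(out2$per_stimulus), 2)
  expect_true(all(out2$per_stimulus$p_bonferroni >=
                    out2$per_stimulus$p_raw))
})
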