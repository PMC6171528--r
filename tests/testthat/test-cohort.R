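small_cfg <- function(seed = 7, ...) {
  cohort_config(n_participants = 30, n_runs = 2, timepoints_per_run = 60,
                seed = seed, ...)
}

test_that("participant generation honours the questionnaire structure", {
  cfg <- cohort_config(n_participants = 818, seed = 1)
  p <- generate_participants(cfg)
  expect_equal(nrow(p), 818)
  traits <- c("neuroticism", "extraversion", "openness", "agreeableness",
              "conscientiousness")
  expect_true(all(traits %in% names(p)))
  items <- attr(p, "items")
  # 60 items per participant, 12 per factor, each on 5 levels 0-4
  expect_equal(dim(items), c(818, 5, 12))
  expect_true(all(items %in% 0:4))
  # factor scores are exact item sums, hence within [0, 48]
  sums <- apply(items, c(1, 2), sum)
  expect_equal(unname(sums), unname(as.matrix(p[, traits])))
  expect_true(all(p[, traits] >= 0 & p[, traits] <= 48))
  expect_true(all(p$age >= 22 & p$age <= 37))
  expect_true(all(p$sex %in% 0:1))
})

test_that("factor scores track the configured distribution at n = 818", {
  p <- generate_participants(cohort_config(n_participants = 818, seed = 2))
  # configured conscientiousness: mean 34, sd 6; MC error ~ 6/sqrt(818)
  expect_lt(abs(mean(p$conscientiousness) - 34), 3 * 6 / sqrt(818))
  expect_lt(abs(sd(p$conscientiousness) - 6), 1)
  # facets load on the conscientiousness factor at the configured 0.7
  expect_gt(cor(p$order, p$conscientiousness), 0.55)
  expect_lt(cor(p$order, p$conscientiousness), 0.85)
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$series, b$series)
  other <- generate_participants(small_cfg(seed = 8))
  expect_false(identical(a$participants$conscientiousness,
                         other$conscientiousness))
})

test_that("configuration errors are caught early", {
  expect_error(cohort_config(likert_levels = 1), class = "micnet_config_error")
  expect_error(cohort_config(n_participants = 0),
               class = "micnet_config_error")
  expect_error(cohort_config(base_coupling = 1.2),
               class = "micnet_config_error")
  expect_error(cohort_config(effect_nodes = "nonexistent"),
               class = "micnet_config_error")
  expect_error(cohort_config(nonlinear_pairs =
                               list(list(pair = c("DMN", "left_FPN"),
                                         form = "cubic"))),
               class = "micnet_config_error")
})

test_that("time series have the configured run geometry", {
  cfg <- cohort_config(n_participants = 2, seed = 3)
  p <- generate_participants(cfg)
  ts <- generate_time_series(p[1, ], cfg, index = 1)
  expect_equal(dim(ts), c(15, 4 * 1200))
  expect_identical(rownames(ts)[1:3], c("left_FPN", "right_FPN", "DMN"))
  expect_true(all(is.finite(ts)))
})

test_that("an inadmissible per-participant coupling names the participant", {
  cfg <- cohort_config(n_participants = 2, base_coupling = 0.9,
                       effect_size = 0.2, seed = 3)
  p <- generate_participants(cfg)
  p$conscientiousness[1] <- 34 + 6 * 4 # z = 4 pushes coupling past 1
  expect_error(generate_time_series(p[1, ], cfg, index = 1),
               "sub_0001", class = "micnet_config_error")
})

test_that("zero effect size leaves coupling unrelated to the trait", {
  cfg <- cohort_config(n_participants = 150, n_runs = 1,
                       timepoints_per_run = 150, effect_size = 0, seed = 10)
  co <- generate_cohort(cfg)
  r_fpn <- vapply(co$series, function(s)
    mean(cor(t(s))["left_FPN", -1]), numeric(1))
  r <- cor(co$participants$conscientiousness, r_fpn)
  expect_lt(abs(r), 3 / sqrt(150))
})

test_that("planted coupling increases with the trait z-score", {
  cfg <- cohort_config(n_participants = 120, n_runs = 1,
                       timepoints_per_run = 200, effect_size = 0.05,
                       seed = 11)
  co <- generate_cohort(cfg)
  r_fpn <- vapply(co$series, function(s)
    mean(cor(t(s))["left_FPN", -c(1, 2, 3)]), numeric(1))
  expect_gt(cor(co$participants$conscientiousness, r_fpn,
                method = "spearman"), 0.3)
  # stronger planting shifts the population mean coupling upward for
  # high-trait participants relative to the zero-effect cohort
  hi <- co$participants$conscientiousness > 40
  expect_gt(mean(r_fpn[hi]), mean(r_fpn[!hi]))
})

test_that("nonlinear pairs carry dependence that survives decorrelation", {
  cfg <- cohort_config(n_participants = 1, n_runs = 1,
                       timepoints_per_run = 400,
                       nonlinear_pairs = list(list(
                         pair = c("node_04", "node_05"),
                         form = "quadratic")),
                       nonlinear_noise_sd = 0.1, base_coupling = 0,
                       seed = 12)
  p <- generate_participants(cfg)
  ts <- generate_time_series(p[1, ], cfg, index = 1)
  a <- ts["node_04", ]; b <- ts["node_05", ]
  expect_lt(abs(cor(a, b)), 0.2)       # linear correlation ~ 0
  expect_gt(mic(a, b), 0.4)            # but MIC sees the quadratic link
})

test_that("cohort files round-trip and degenerate writes are refused", {
  cfg <- small_cfg()
  co <- generate_cohort(cfg)
  co$participants <- co$participants[1:3, ]
  co$series <- co$series[1:3]
  dir <- withr::local_tempdir()
  write_cohort(co$participants, co$series, dir)
  expect_true(file.exists(file.path(dir, "participants.csv")))
  expect_length(list.files(file.path(dir, "timeseries")), 3)
  p2 <- read_participants(file.path(dir, "participants.csv"))
  expect_equal(p2, co$participants, ignore_attr = TRUE)
  ts2 <- read_time_series(file.path(dir, "timeseries", "sub_0001.tsv"))
  expect_equal(ts2, co$series[["sub_0001"]])
  # write -> read -> write is byte-stable
  dir2 <- withr::local_tempdir()
  ser2 <- lapply(p2$participant_id, function(id)
    read_time_series(file.path(dir, "timeseries", paste0(id, ".tsv"))))
  names(ser2) <- p2$participant_id
  write_cohort(p2, ser2, dir2)
  for (f in c("participants.csv", file.path("timeseries", "sub_0001.tsv")))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  expect_error(write_cohort(co$participants[0, ], list(), dir),
               class = "micnet_data_error")
  dup <- co$participants
  dup$participant_id[2] <- dup$participant_id[1]
  expect_error(write_cohort(dup, co$series, dir),
               class = "micnet_data_error")
})
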