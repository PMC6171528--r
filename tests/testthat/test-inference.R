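test_that("train/test split reproduces the 70/30 bookkeeping", {
  ids <- sprintf("s%03d", 1:818)
  sp <- split_sample(ids, 0.7, seed = 1)
  expect_length(sp$train, 573)
  expect_length(sp$test, 245)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  sp10 <- split_sample(sprintf("s%d", 1:10), 0.7, seed = 2)
  expect_length(sp10$train, 7)
  expect_length(sp10$test, 3)
  expect_identical(split_sample(ids, 0.7, seed = 5),
                   split_sample(ids, 0.7, seed = 5))
  expect_error(split_sample("a", 0.5), class = "micnet_config_error")
  expect_error(split_sample(c("a", "b"), 0.99),
               class = "micnet_config_error")
})

test_that("OLS recovers exact linear structure and matches lm()", {
  set.seed(1)
  n <- 80
  design <- cbind(intercept = 1,
                  conscientiousness = scale(rnorm(n))[, 1],
                  age = scale(rnorm(n))[, 1],
                  sex = rbinom(n, 1, 0.5))
  y <- 2 * design[, "conscientiousness"]
  fit <- fit_glm(y, design)
  cf <- fit$coefficients
  expect_equal(cf$beta[cf$predictor == "conscientiousness"], 2,
               tolerance = 1e-10)
  expect_lt(max(abs(cf$beta[cf$predictor != "conscientiousness"])), 1e-10)
  # independent oracle: R's own linear-model machinery
  y2 <- 0.5 * design[, 2] + rnorm(n)
  fit2 <- fit_glm(y2, design)
  ref <- summary(lm(y2 ~ design[, -1]))$coefficients
  expect_equal(fit2$coefficients$beta, unname(ref[, 1]), tolerance = 1e-12)
  expect_equal(fit2$coefficients$se, unname(ref[, 2]), tolerance = 1e-12)
  expect_equal(fit2$coefficients$p, unname(ref[, 4]), tolerance = 1e-12)
  # rank deficiency names the collinear column
  bad <- cbind(design, dup = design[, "conscientiousness"])
  expect_error(fit_glm(y2, bad), "dup", class = "micnet_data_error")
})

test_that("OLS estimates are unbiased with nominal CI coverage", {
  set.seed(21)
  n <- 60
  design <- cbind(intercept = 1, x = rnorm(n), z = rnorm(n))
  betas <- numeric(300)
  cover <- logical(300)
  for (r in 1:300) {
    y <- 1 + 0.4 * design[, "x"] + rnorm(n)
    fit <- fit_glm(y, design)
    cf <- fit$coefficients[fit$coefficients$predictor == "x", ]
    betas[r] <- cf$beta
    ci <- cf$beta + c(-1, 1) * qt(0.975, fit$df_residual) * cf$se
    cover[r] <- ci[1] <= 0.4 && 0.4 <= ci[2]
  }
  expect_lt(abs(mean(betas) - 0.4), 3 * sd(betas) / sqrt(300))
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("BH correction matches the hand-evaluated step-up example", {
  res <- fdr_correct(c(0.001, 0.008, 0.039, 0.041, 0.5), q_threshold = 0.05)
  expect_equal(sum(res$significant), 2)
  expect_equal(res$q[1], 0.005)
  res1 <- fdr_correct(1)
  expect_equal(res1$q, 1)
  expect_false(any(fdr_correct(rep(1, 8))$significant))
  expect_equal(fdr_correct(0.03)$q, 0.03) # m = 1
  expect_length(fdr_correct(numeric(0))$q, 0)
})

test_that("BH correction agrees with a brute-force step-up", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(fdr_correct(p)$q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("RRMSE matches its definition and error contracts", {
  obs <- c(1, 2, 3)
  expect_equal(rrmse(obs, obs), 0)
  expect_equal(rrmse(obs, c(0, 0, 0)), 1)
  expect_equal(rrmse(obs, c(1, 2, 4)), sqrt(1 / 14), tolerance = 1e-12)
  expect_error(rrmse(c(0, 0), c(1, 1)), class = "micnet_data_error")
  expect_error(rrmse(1, 1), class = "micnet_data_error")
  expect_equal(rrmse(obs, c(1, 2, 4), norm = "mean"),
               sqrt(1 / 3) / 2, tolerance = 1e-12)
  expect_equal(rrmse(obs, c(1, 2, 4), norm = "range"),
               sqrt(1 / 3) / 2, tolerance = 1e-12)
})

test_that("the association scan keeps its bookkeeping straight", {
  parts <- sim_participants(60, seed = 41)
  tabs <- sim_metric_tables(parts, seed = 42)
  scan <- run_association_scan(tabs$metrics, tabs$globals, parts, seed = 1)
  traits <- c("neuroticism", "extraversion", "openness", "agreeableness",
              "conscientiousness")
  tested <- scan$associations[scan$associations$predictor ==
                                scan$associations$family, ]
  expect_equal(nrow(tested), 5 * 63) # one FDR family per trait, 63 outcomes
  expect_true(all(!is.na(tested$q)))
  expect_true(all(tested$q >= tested$p - 1e-12))
  expect_equal(nrow(scan$validation), 5 * 63)
  expect_s3_class(scan, "trait_scan")
  expect_output(print(scan), "association scan")
})

test_that("a strong planted effect is flagged and localized", {
  parts <- sim_participants(300, seed = 51)
  tabs <- sim_metric_tables(parts, planted = "left_FPN.strength",
                            partial_r = 0.35, seed = 52)
  scan <- run_association_scan(tabs$metrics, tabs$globals, parts, seed = 3)
  hit <- scan$associations[scan$associations$family == "conscientiousness" &
                             scan$associations$predictor ==
                               "conscientiousness" &
                             scan$associations$outcome ==
                               "left_FPN.strength", ]
  expect_true(hit$significant)
  expect_gt(hit$beta, 0)
  # other traits stay quiet
  other <- scan$associations[scan$associations$family == "extraversion" &
                               !is.na(scan$associations$significant), ]
  expect_lt(sum(other$significant), 3)
})

test_that("test-split predictions never touch test-split metrics", {
  parts <- sim_participants(80, seed = 61)
  tabs <- sim_metric_tables(parts, seed = 62)
  sp <- split_sample(parts$participant_id, 0.7, seed = 4)
  scan <- run_association_scan(tabs$metrics, tabs$globals, parts, split = sp)
  # poison every test-split metric value; fits and predictions must be
  # unchanged, proving the fit reads training data only
  poisoned <- tabs
  sel <- poisoned$metrics$participant_id %in% sp$test
  mets <- c("strength", "clustering", "local_efficiency", "betweenness")
  poisoned$metrics[sel, mets] <- poisoned$metrics[sel, mets] + 1000
  scan2 <- run_association_scan(poisoned$metrics, tabs$globals, parts,
                                split = sp)
  expect_identical(coef(scan), coef(scan2))
  expect_identical(scan$associations, scan2$associations)
  pred1 <- predict(scan, parts[parts$participant_id %in% sp$test, ])
  pred2 <- predict(scan2, parts[parts$participant_id %in% sp$test, ])
  expect_identical(pred1, pred2)
  # but the poisoned observations do change the reported validation error
  expect_false(identical(scan$validation$rrmse, scan2$validation$rrmse))
})

test_that("prediction is the linear map of standardized covariates", {
  parts <- sim_participants(50, seed = 71)
  tabs <- sim_metric_tables(parts, seed = 72)
  sp <- split_sample(parts$participant_id, 0.7, seed = 5)
  scan <- run_association_scan(tabs$metrics, tabs$globals, parts, split = sp)
  fam <- "conscientiousness"
  mod <- scan$models[[fam]]
  # matrix-product oracle
  te <- parts[parts$participant_id %in% sp$test, ]
  pred <- predict(scan, te, family = fam)
  cont <- setdiff(mod$design_cols, c("intercept", "sex"))
  x <- as.matrix(te[, cont])
  xs <- sweep(sweep(x, 2, mod$params$center), 2, mod$params$scale, "/")
  oracle <- cbind(1, xs, te$sex) %*% mod$beta
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-12)
  # a training participant's covariates reproduce the fitted value
  tr1 <- parts[parts$participant_id == sp$train[1], ]
  p1 <- predict(scan, tr1, family = fam)
  fitv <- {
    all_tr <- parts[parts$participant_id %in% sp$train, ]
    d <- cbind(1, sweep(sweep(as.matrix(all_tr[, cont]), 2,
                              mod$params$center), 2,
                        mod$params$scale, "/"), all_tr$sex)
    (d %*% mod$beta)[match(tr1$participant_id, all_tr$participant_id), ]
  }
  expect_equal(unname(p1[1, ]), unname(fitv), tolerance = 1e-12)
  # all-zero standardized covariates predict the intercept row
  mid <- tr1
  mid[cont] <- as.list(mod$params$center)
  mid$sex <- 0
  expect_equal(unname(predict(scan, mid, family = fam)[1, ]),
               unname(mod$beta["intercept", ]), tolerance = 1e-12)
})

test_that("facet scan runs four families and rejects collinear designs", {
  parts <- sim_participants(70, seed = 81)
  tabs <- sim_metric_tables(parts, seed = 82)
  scan <- facet_scan(tabs$metrics, tabs$globals, parts, seed = 6)
  expect_setequal(unique(scan$associations$family),
                  c("order", "dutifulness", "achievement_striving",
                    "self_discipline"))
  tested <- scan$associations[scan$associations$predictor ==
                                scan$associations$family, ]
  expect_equal(nrow(tested), 4 * 63)
  # conscientiousness itself is not in the facet designs
  expect_false("conscientiousness" %in% scan$associations$predictor)
  bad <- parts
  bad$order <- bad$neuroticism # exact collinearity with a nuisance trait
  expect_error(facet_scan(tabs$metrics, tabs$globals, bad, seed = 6),
               "rank deficient", class = "micnet_data_error")
})

test_that("validation error degrades as signal is replaced by noise", {
  parts <- sim_participants(200, seed = 91)
  strong <- sim_metric_tables(parts, planted = "left_FPN.strength",
                              partial_r = 0.6, seed = 92)
  none <- sim_metric_tables(parts, planted = "left_FPN.strength",
                            partial_r = 0, seed = 92)
  sp <- split_sample(parts$participant_id, 0.7, seed = 7)
  s1 <- run_association_scan(strong$metrics, strong$globals, parts,
                             split = sp)
  s0 <- run_association_scan(none$metrics, none$globals, parts, split = sp)
  pick <- function(s) s$validation$rrmse[s$validation$family ==
                                           "conscientiousness" &
                                           s$validation$outcome ==
                                             "left_FPN.strength"]
  expect_lt(pick(s1), pick(s0))
})
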