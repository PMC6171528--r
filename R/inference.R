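#' Random train/test split
#'
#' Partitions participant ids into a training and a test set. The training
#' size is `round(train_fraction * n)` with halves rounded up, so an
#' 818-participant cohort at 70% yields 573 training and 245 test
#' participants.
#'
#' @param participant_ids Character vector (at least 2, no duplicates).
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed Integer seed for the permutation.
#' @return List with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_sample <- function(participant_ids, train_fraction = 0.7, seed = 1) {
  n <- length(participant_ids)
  if (n < 2) stop_config("need at least 2 participants to split")
  if (anyDuplicated(participant_ids)) stop_data("duplicate participant ids")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction must be in (0, 1)")
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  if (n_train == 0 || n_train == n)
    stop_config("split leaves one side empty")
  set.seed(seed)
  train <- sort(sample(participant_ids, n_train))
  list(train = train, test = sort(setdiff(participant_ids, train)))
}

#' Ordinary-least-squares fit with per-coefficient inference
#'
#' Fits `outcome ~ design` by OLS and returns, per column of the design,
#' the coefficient, its standard error, the t statistic on `n - p`
#' residual degrees of freedom, and the two-sided p value.
#'
#' @param outcome Numeric response vector.
#' @param design Numeric model matrix including its intercept column; must
#'   have full column rank and more rows than columns.
#' @return List with `coefficients` (data frame: predictor, beta, se, t,
#'   p), `fitted`, `residuals`, `sigma2`, `df_residual`.
#' @export
fit_glm <- function(outcome, design) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (length(outcome) != n) stop_data("outcome length does not match design")
  if (n <= p) stop_data("need more observations than predictors")
  qrd <- qr(design)
  if (qrd$rank < p) {
    bad <- colnames(design)[setdiff(seq_len(p), qrd$pivot[seq_len(qrd$rank)])]
    stop_data("design matrix is rank deficient; collinear columns: ",
              paste(bad, collapse = ", "))
  }
  fit <- lm.fit(design, outcome)
  df <- n - p
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  beta <- fit$coefficients
  if (sigma2 == 0) {
    # perfect fit (e.g. a constant outcome): no sampling variability; a
    # zero coefficient carries no evidence, a nonzero one is exact
    tval <- ifelse(beta == 0, 0, sign(beta) * Inf)
    pval <- ifelse(beta == 0, 1, 0)
  } else {
    tval <- beta / se
    pval <- 2 * pt(-abs(tval), df)
  }
  list(coefficients = data.frame(predictor = colnames(design), beta = beta,
                                 se = se, t = tval, p = pval,
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       fitted = drop(design %*% beta), residuals = fit$residuals,
       sigma2 = sigma2, df_residual = df)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment: with `m` p values sorted ascending, the adjusted
#' value is `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. A result is
#' flagged significant when `q < q_threshold`.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @param q_threshold FDR level (default .01, the stringent threshold used
#'   throughout this package).
#' @return List with `q` (adjusted values, same order as input) and
#'   `significant` (logical mask).
#' @export
fdr_correct <- function(p_values, q_threshold = 0.01) {
  if (length(p_values) == 0)
    return(list(q = numeric(0), significant = logical(0)))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop_data("p values must lie in [0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q = q, significant = q < q_threshold)
}

#' Relative root-mean-square error
#'
#' Prediction error normalized by the scale of the observations:
#' \deqn{RRMSE = \sqrt{\frac{1}{n}\sum (y_i - \hat y_i)^2} \Big/
#'   \sqrt{\frac{1}{n}\sum y_i^2}} for `norm = "rms"` (the default; a
#' zero predictor then scores exactly 1). `norm = "mean"` divides the RMSE
#' by `|mean(y)|` and `norm = "range"` by `max(y) - min(y)`.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`.
#' @param norm Normalization: `"rms"`, `"mean"` or `"range"`.
#' @return Non-negative scalar; 0 exactly when predictions equal
#'   observations.
#' @export
rrmse <- function(observed, predicted, norm = c("rms", "mean", "range")) {
  norm <- match.arg(norm)
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop_data("observed and predicted must have equal length >= 2")
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- switch(norm,
                  rms = sqrt(mean(observed^2)),
                  mean = abs(mean(observed)),
                  range = diff(range(observed)))
  if (denom == 0)
    stop_data("observations carry no scale under norm = '", norm, "'")
  rmse / denom
}

# ---- association scan -------------------------------------------------

# wide outcome matrix (participants x 63 outcomes) from long local metrics
# + globals tables
outcome_matrix <- function(metrics, globals) {
  need <- c("participant_id", "node", "strength", "clustering",
            "local_efficiency", "betweenness")
  missing <- setdiff(need, names(metrics))
  if (length(missing))
    stop_data("metrics table lacks columns: ", paste(missing, collapse = ", "))
  ids <- unique(metrics$participant_id)
  nodes <- unique(metrics$node)
  mets <- c("strength", "clustering", "local_efficiency", "betweenness")
  out <- matrix(NA_real_, length(ids), length(nodes) * length(mets) + 3L)
  rownames(out) <- ids
  cn <- character(0)
  col <- 0L
  for (m in mets) {
    for (nd in nodes) {
      col <- col + 1L
      cn[col] <- paste(nd, m, sep = ".")
      rows <- metrics[metrics$node == nd, c("participant_id", m)]
      out[rows$participant_id, col] <- rows[[m]]
    }
  }
  gcols <- c("global_strength", "global_clustering", "global_efficiency")
  gmiss <- setdiff(c("participant_id", gcols), names(globals))
  if (length(gmiss))
    stop_data("globals table lacks columns: ", paste(gmiss, collapse = ", "))
  for (gc in gcols) {
    col <- col + 1L
    cn[col] <- gc
    out[globals$participant_id, col] <- globals[[gc]]
  }
  colnames(out) <- cn
  if (anyNA(out)) stop_data("metrics are missing for some participants")
  out
}

standardize_covariates <- function(participants, continuous, params = NULL) {
  x <- as.matrix(participants[, continuous, drop = FALSE])
  if (is.null(params))
    params <- list(center = colMeans(x), scale = apply(x, 2L, sd))
  if (any(params$scale == 0))
    stop_data("constant covariate cannot be standardized: ",
              paste(continuous[params$scale == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2L, params$center), 2L, params$scale, "/")
  list(x = xs, params = params)
}

build_design <- function(participants, continuous, params = NULL) {
  missing <- setdiff(c(continuous, "sex"), names(participants))
  if (length(missing))
    stop_data("participants table lacks covariates: ",
              paste(missing, collapse = ", "))
  if (anyNA(participants[, c(continuous, "sex")]))
    stop_data("missing covariate values")
  std <- standardize_covariates(participants, continuous, params)
  design <- cbind(intercept = 1, std$x, sex = participants$sex)
  rownames(design) <- participants$participant_id
  list(design = design, params = std$params)
}

scan_engine <- function(outcomes, participants, families, nuisance,
                        train_ids, test_ids, fdr_q, rrmse_norm) {
  participants <- participants[match(rownames(outcomes),
                                     participants$participant_id), ]
  if (anyNA(participants$participant_id))
    stop_data("covariates missing for some participants with metrics")
  in_train <- rownames(outcomes) %in% train_ids
  in_test <- rownames(outcomes) %in% test_ids
  if (!any(in_train) || !any(in_test)) stop_data("empty split side")
  results <- list()
  beta_store <- list()
  # families: named list, each = the predictor of interest for that family;
  # nuisance: named list of that family's continuous nuisance covariates
  # (age is always included; sex enters unstandardized)
  for (fam in names(families)) {
    continuous <- unique(c(families[[fam]], nuisance[[fam]], "age"))
    tr <- build_design(participants[in_train, ], continuous)
    rows <- lapply(colnames(outcomes), function(oc) {
      fit <- fit_glm(outcomes[in_train, oc], tr$design)
      cf <- fit$coefficients
      cf$outcome <- oc
      cf
    })
    tab <- do.call(rbind, rows)
    tab$family <- fam
    fam_rows <- tab$predictor == families[[fam]]
    adj <- fdr_correct(tab$p[fam_rows], fdr_q)
    tab$q <- NA_real_
    tab$significant <- NA
    tab$q[fam_rows] <- adj$q
    tab$significant[fam_rows] <- adj$significant
    results[[fam]] <- tab
    # prediction on the held-out sample: covariates standardized with the
    # training parameters; imaging-derived outcomes of the test side are
    # used only as the comparison target for RRMSE
    te <- build_design(participants[in_test, ], continuous,
                       params = tr$params)
    beta <- vapply(rows, function(r) r$beta, numeric(ncol(tr$design)))
    colnames(beta) <- colnames(outcomes)
    rownames(beta) <- colnames(tr$design)
    pred <- te$design %*% beta
    val <- data.frame(outcome = colnames(outcomes),
                      family = fam,
                      rrmse = vapply(colnames(outcomes), function(oc)
                        tryCatch(rrmse(outcomes[in_test, oc], pred[, oc],
                                       norm = rrmse_norm),
                                 micnet_data_error = function(e) NA_real_),
                        numeric(1)),
                      n_test = sum(in_test),
                      row.names = NULL, stringsAsFactors = FALSE)
    beta_store[[fam]] <- list(beta = beta, params = tr$params,
                              design_cols = colnames(tr$design),
                              validation = val)
  }
  assoc <- do.call(rbind, results)
  rownames(assoc) <- NULL
  node_metric <- strsplit(assoc$outcome, ".", fixed = TRUE)
  assoc$node <- vapply(node_metric, function(v)
    if (length(v) == 2) v[1] else "global", character(1))
  assoc$metric <- vapply(node_metric, function(v)
    if (length(v) == 2) v[2] else v[1], character(1))
  assoc <- assoc[, c("outcome", "node", "metric", "family", "predictor",
                     "beta", "se", "t", "p", "q", "significant")]
  validation <- do.call(rbind, lapply(beta_store, `[[`, "validation"))
  rownames(validation) <- NULL
  structure(list(associations = assoc,
                 validation = validation,
                 models = beta_store,
                 train_ids = train_ids, test_ids = test_ids,
                 fdr_q = fdr_q, rrmse_norm = rrmse_norm,
                 families = families, nuisance = nuisance),
            class = "trait_scan")
}

#' Trait-connectome association scan with external validation
#'
#' Fits, on the training split only, one linear model per graph-measure
#' outcome (by default 15 nodes x 4 local measures + 3 global measures =
#' 63 outcomes) with the five personality traits plus age and sex as
#' predictors; continuous predictors are z-scored on the training sample.
#' P values are FDR-adjusted per trait across that trait's 63 outcomes
#' (Benjamini-Hochberg), with significance at `q < fdr_q`. The fitted
#' models then predict every outcome for the held-out test split from
#' covariates alone, and prediction quality is scored by [rrmse()] —
#' external validation: test-split connectivity data never enter the fit.
#'
#' @param metrics Long local-metrics table (`participant_id`, `node`,
#'   `strength`, `clustering`, `local_efficiency`, `betweenness`).
#' @param globals Global-metrics table (`participant_id`,
#'   `global_strength`, `global_clustering`, `global_efficiency`).
#' @param participants Covariate table from [generate_participants()] /
#'   [read_participants()].
#' @param train_fraction,seed Passed to [split_sample()]; ignored when
#'   `split` is given.
#' @param split Optional precomputed list with `train` and `test` id
#'   vectors.
#' @param fdr_q FDR significance threshold.
#' @param rrmse_norm RRMSE normalization (see [rrmse()]).
#' @return A `trait_scan` object: `associations` (long table with beta,
#'   se, t, p, q, significance per predictor and outcome), `validation`
#'   (per-outcome RRMSE on the test split) and the fitted model
#'   coefficients. Has `print()`, `summary()`, `coef()` and `predict()`
#'   methods.
#' @export
run_association_scan <- function(metrics, globals, participants,
                                 train_fraction = 0.7, seed = 1,
                                 split = NULL, fdr_q = 0.01,
                                 rrmse_norm = "rms") {
  outcomes <- outcome_matrix(metrics, globals)
  if (is.null(split))
    split <- split_sample(rownames(outcomes), train_fraction, seed)
  traits <- trait_names()
  families <- stats::setNames(as.list(traits), traits)
  # every family's design holds all five traits plus age and sex; the
  # family only determines which predictor's p values form the FDR family
  nuisance <- lapply(traits, function(t) setdiff(traits, t))
  names(nuisance) <- traits
  scan_engine(outcomes, participants, families, nuisance = nuisance,
              train_ids = split$train, test_ids = split$test,
              fdr_q = fdr_q, rrmse_norm = rrmse_norm)
}

#' @export
print.trait_scan <- function(x, ...) {
  nsig <- sum(x$associations$significant, na.rm = TRUE)
  cat("Trait-connectome association scan\n")
  cat(sprintf("  training n = %d, test n = %d\n", length(x$train_ids),
              length(x$test_ids)))
  cat(sprintf("  %d outcomes x %d families; %d association(s) significant at q < %g\n",
              nrow(x$validation) / length(x$families), length(x$families),
              nsig, x$fdr_q))
  cat(sprintf("  median test-split RRMSE = %.3f (%s norm)\n",
              stats::median(x$validation$rrmse, na.rm = TRUE), x$rrmse_norm))
  invisible(x)
}

#' @export
summary.trait_scan <- function(object, ...) {
  sig <- object$associations[which(object$associations$significant), ]
  sig <- sig[order(sig$q, sig$p), ]
  out <- list(significant = sig,
              rrmse = stats::setNames(object$validation$rrmse,
                                      paste(object$validation$family,
                                            object$validation$outcome,
                                            sep = ":")),
              fdr_q = object$fdr_q)
  class(out) <- "summary.trait_scan"
  out
}

#' @export
print.summary.trait_scan <- function(x, ...) {
  if (nrow(x$significant) == 0) {
    cat("No associations significant at q <", x$fdr_q, "\n")
  } else {
    cat("Associations significant at q <", x$fdr_q, "\n")
    print(x$significant[, c("outcome", "family", "beta", "t", "p", "q")],
          row.names = FALSE, digits = 3)
  }
  cat(sprintf("RRMSE over outcomes: median %.3f, range %.3f-%.3f\n",
              stats::median(x$rrmse, na.rm = TRUE), min(x$rrmse, na.rm = TRUE),
              max(x$rrmse, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.trait_scan <- function(object, family = NULL, ...) {
  if (is.null(family)) family <- names(object$models)[1]
  object$models[[family]]$beta
}

#' Predict graph measures for new participants
#'
#' Applies the training-split standardization and fitted coefficients to a
#' new covariate table; no imaging-derived input is used.
#'
#' @param object A `trait_scan`.
#' @param newdata Covariate table with the predictor columns.
#' @param family Which predictor family's model to use (default: first).
#' @param ... Unused.
#' @return Matrix of predicted outcomes (participants x outcomes).
#' @export
predict.trait_scan <- function(object, newdata, family = NULL, ...) {
  if (is.null(family)) family <- names(object$models)[1]
  mod <- object$models[[family]]
  continuous <- setdiff(mod$design_cols, c("intercept", "sex"))
  d <- build_design(newdata, continuous, params = mod$params)
  if (!identical(colnames(d$design), mod$design_cols))
    stop_data("covariate columns do not match the fitted design")
  d$design %*% mod$beta
}

#' Conscientiousness-facet association scan
#'
#' Post hoc analysis: one model family per conscientiousness facet
#' (Order, Dutifulness, Achievement striving, Self-Discipline), each fit
#' with the facet of interest plus the four non-conscientiousness traits,
#' age and sex as covariates. The conscientiousness total score is
#' excluded — its facets are components of it and would be collinear. FDR
#' is applied within each facet's outcome family.
#'
#' @inheritParams run_association_scan
#' @return A `trait_scan` object with four facet families.
#' @export
facet_scan <- function(metrics, globals, participants,
                       train_fraction = 0.7, seed = 1, split = NULL,
                       fdr_q = 0.01, rrmse_norm = "rms") {
  missing <- setdiff(facet_names(), names(participants))
  if (length(missing))
    stop_data("participants table lacks facet columns: ",
              paste(missing, collapse = ", "))
  outcomes <- outcome_matrix(metrics, globals)
  if (is.null(split))
    split <- split_sample(rownames(outcomes), train_fraction, seed)
  families <- stats::setNames(as.list(facet_names()), facet_names())
  nuisance <- lapply(families, function(f)
    setdiff(trait_names(), "conscientiousness"))
  scan_engine(outcomes, participants, families, nuisance = nuisance,
              train_ids = split$train, test_ids = split$test,
              fdr_q = fdr_q, rrmse_norm = rrmse_norm)
}
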