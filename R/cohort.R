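#' @keywords internal
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("micnet_config_error", "error")))
}

#' @keywords internal
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("micnet_data_error", "error")))
}

default_node_labels <- function(n_nodes) {
  stand_ins <- c("left_FPN", "right_FPN", "DMN")
  if (n_nodes <= length(stand_ins)) return(stand_ins[seq_len(n_nodes)])
  c(stand_ins, sprintf("node_%02d", seq.int(length(stand_ins) + 1, n_nodes)))
}

trait_names <- function() {
  c("neuroticism", "extraversion", "openness", "agreeableness",
    "conscientiousness")
}

facet_names <- function() {
  c("order", "dutifulness", "achievement_striving", "self_discipline")
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults reproduce
#' the geometry of the emulated study inputs: 818 participants aged 22-37,
#' 15 network-node time series of 4 runs x 1,200 timepoints each, and
#' five-factor trait scores built from 12 five-point Likert items per
#' factor (scores on a 0-48 sum scale). The trait means/SDs are plausible
#' NEO-FFI adult norms, not estimates from any particular cohort; all are
#' configurable.
#'
#' The planted association works through inter-node coupling: each
#' `effect_nodes` member's correlation with every other node is
#' `base_coupling + effect_size * z`, where `z` is the participant's
#' standardized `effect_trait` score. `nonlinear_pairs` optionally replace
#' the linear coupling of chosen node pairs with a quadratic or sinusoidal
#' dependence, so the detector's sensitivity beyond linearity can be
#' exercised.
#'
#' @param n_participants Cohort size.
#' @param n_nodes Number of network nodes.
#' @param n_runs,timepoints_per_run Scanning-session geometry; runs are
#'   generated independently and concatenated.
#' @param base_coupling Baseline inter-node correlation in (-1, 1).
#' @param effect_nodes Labels of the nodes whose coupling is modulated by
#'   the trait (defaults: the fronto-parietal and default-mode stand-ins).
#' @param effect_trait Trait doing the modulating.
#' @param effect_size Coupling increment per SD of the trait.
#' @param nonlinear_pairs List of `list(pair = c(a, b), form =
#'   "quadratic"|"sinusoidal")` entries.
#' @param nonlinear_noise_sd SD of the additive noise on nonlinear pairs.
#' @param noise_sd Marginal SD of each node signal.
#' @param likert_levels Number of response levels per item (>= 2).
#' @param items_per_factor Items summed into each factor score.
#' @param item_level If `FALSE`, trait scores are drawn directly from the
#'   (rounded, clamped) Gaussian instead of being assembled from items.
#' @param trait_means,trait_sds Named numeric vectors over the five
#'   factors, on the item-sum scale.
#' @param facet_loading Correlation between each conscientiousness facet
#'   and the conscientiousness factor score.
#' @param facet_means,facet_sds Named numeric vectors over the four facets.
#' @param sex_trait_shift Named numeric vector: additive shift of the trait
#'   mean for participants coded `sex = 1` (all zero by default, so sex is
#'   independent of traits unless a confound is requested).
#' @param age_range Two integers, inclusive.
#' @param seed Integer seed governing all cohort randomness.
#' @return A classed list (`cohort_config`).
#' @export
cohort_config <- function(n_participants = 818,
                          n_nodes = 15,
                          n_runs = 4,
                          timepoints_per_run = 1200,
                          base_coupling = 0.3,
                          effect_nodes = c("left_FPN", "right_FPN", "DMN"),
                          effect_trait = "conscientiousness",
                          effect_size = 0,
                          nonlinear_pairs = list(),
                          nonlinear_noise_sd = 0.3,
                          noise_sd = 1,
                          likert_levels = 5,
                          items_per_factor = 12,
                          item_level = TRUE,
                          trait_means = c(neuroticism = 17, extraversion = 30,
                                          openness = 29, agreeableness = 33,
                                          conscientiousness = 34),
                          trait_sds = c(neuroticism = 8, extraversion = 6,
                                        openness = 6, agreeableness = 5,
                                        conscientiousness = 6),
                          facet_loading = 0.7,
                          facet_means = c(order = 16, dutifulness = 16,
                                          achievement_striving = 16,
                                          self_discipline = 16),
                          facet_sds = c(order = 4, dutifulness = 4,
                                        achievement_striving = 4,
                                        self_discipline = 4),
                          sex_trait_shift = c(neuroticism = 0,
                                              extraversion = 0, openness = 0,
                                              agreeableness = 0,
                                              conscientiousness = 0),
                          age_range = c(22, 37),
                          seed = 1) {
  if (likert_levels < 2) stop_config("likert_levels must be at least 2")
  if (n_participants < 1) stop_config("n_participants must be at least 1")
  if (n_nodes < 2) stop_config("n_nodes must be at least 2")
  if (abs(base_coupling) >= 1) stop_config("base_coupling must be in (-1, 1)")
  if (noise_sd <= 0) stop_config("noise_sd must be positive")
  if (!effect_trait %in% trait_names())
    stop_config("unknown effect_trait: ", effect_trait)
  labels <- default_node_labels(n_nodes)
  if (!all(effect_nodes %in% labels))
    stop_config("effect_nodes not among node labels: ",
                paste(setdiff(effect_nodes, labels), collapse = ", "))
  for (nl in nonlinear_pairs) {
    if (!is.list(nl) || !all(c("pair", "form") %in% names(nl)) ||
        length(nl$pair) != 2 || !all(nl$pair %in% labels) ||
        !nl$form %in% c("quadratic", "sinusoidal"))
      stop_config("each nonlinear_pairs entry needs pair (2 node labels) ",
                  "and form in {quadratic, sinusoidal}")
  }
  for (nm in list(trait_means, trait_sds, sex_trait_shift)) {
    if (!all(trait_names() %in% names(nm)))
      stop_config("trait parameter vectors must name all five factors")
  }
  cfg <- list(n_participants = as.integer(n_participants),
              n_nodes = as.integer(n_nodes),
              n_runs = as.integer(n_runs),
              timepoints_per_run = as.integer(timepoints_per_run),
              base_coupling = base_coupling,
              effect_nodes = effect_nodes,
              effect_trait = effect_trait,
              effect_size = effect_size,
              nonlinear_pairs = nonlinear_pairs,
              nonlinear_noise_sd = nonlinear_noise_sd,
              noise_sd = noise_sd,
              likert_levels = as.integer(likert_levels),
              items_per_factor = as.integer(items_per_factor),
              item_level = isTRUE(item_level),
              trait_means = trait_means[trait_names()],
              trait_sds = trait_sds[trait_names()],
              facet_loading = facet_loading,
              facet_means = facet_means[facet_names()],
              facet_sds = facet_sds[facet_names()],
              sex_trait_shift = sex_trait_shift[trait_names()],
              age_range = as.integer(age_range),
              node_labels = labels,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  # the zero-effect coupling matrix must itself be admissible
  base <- coupling_matrix(cfg, z = 0)
  if (!is_positive_definite(base))
    stop_config("implied inter-node correlation matrix is not positive ",
                "definite under base_coupling = ", base_coupling)
  cfg
}

coupling_matrix <- function(config, z) {
  n <- config$n_nodes
  r <- matrix(config$base_coupling, n, n)
  eff <- match(config$effect_nodes, config$node_labels)
  val <- config$base_coupling + config$effect_size * z
  r[eff, ] <- val
  r[, eff] <- val
  diag(r) <- 1
  dimnames(r) <- list(config$node_labels, config$node_labels)
  r
}

is_positive_definite <- function(m) {
  ev <- tryCatch(chol(m), error = function(e) NULL)
  !is.null(ev)
}

# decompose an integer total in [0, k*(L-1)] into k item scores in [0, L-1],
# summing exactly to the total, then shuffle mass between item pairs so the
# item profile is not degenerate
split_items <- function(total, k, levels) {
  maxlev <- levels - 1L
  base <- total %/% k
  rem <- total %% k
  items <- rep.int(base, k)
  if (rem > 0) items[sample.int(k, rem)] <- base + 1L
  for (t in seq_len(2L * k)) {
    ij <- sample.int(k, 2L)
    if (items[ij[1]] > 0L && items[ij[2]] < maxlev) {
      items[ij[1]] <- items[ij[1]] - 1L
      items[ij[2]] <- items[ij[2]] + 1L
    }
  }
  items
}

#' Generate participant records
#'
#' Draws a synthetic cohort of demographic covariates and personality
#' scores. Each factor score targets a Gaussian with the configured
#' mean/SD, rounded and clamped to the attainable item-sum range; with
#' item-level generation enabled the score is then decomposed into
#' `items_per_factor` Likert responses that sum to it exactly, mirroring
#' how NEO-FFI factor scores are assembled from 12 five-point items.
#' Conscientiousness facet scores load on the standardized
#' conscientiousness factor at `facet_loading`.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `participant_id`, `age`, `sex`, the
#'   five trait scores and the four facet scores. When item-level
#'   generation is on, the item responses are attached as attribute
#'   `"items"` (an `n x factor x item` array).
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  set.seed(config$seed)
  id <- sprintf("sub_%04d", seq_len(n))
  age <- sample(seq.int(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  sex <- rbinom(n, 1L, 0.5)
  maxsum <- config$items_per_factor * (config$likert_levels - 1L)
  scores <- matrix(NA_real_, n, 5L,
                   dimnames = list(NULL, trait_names()))
  items <- NULL
  if (config$item_level)
    items <- array(NA_integer_,
                   dim = c(n, 5L, config$items_per_factor),
                   dimnames = list(id, trait_names(), NULL))
  for (f in trait_names()) {
    mu <- config$trait_means[[f]] + config$sex_trait_shift[[f]] * sex
    raw <- rnorm(n, mu, config$trait_sds[[f]])
    tot <- as.integer(pmin(pmax(round(raw), 0), maxsum))
    if (config$item_level) {
      for (i in seq_len(n))
        items[i, f, ] <- split_items(tot[i], config$items_per_factor,
                                     config$likert_levels)
      scores[, f] <- apply(items[, f, , drop = FALSE], 1L, sum)
    } else {
      scores[, f] <- tot
    }
  }
  zc <- (scores[, "conscientiousness"] -
           config$trait_means[["conscientiousness"]]) /
    config$trait_sds[["conscientiousness"]]
  lam <- config$facet_loading
  facets <- sapply(facet_names(), function(f) {
    config$facet_means[[f]] + config$facet_sds[[f]] *
      (lam * zc + sqrt(1 - lam^2) * rnorm(n))
  })
  out <- data.frame(participant_id = id, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores), as.data.frame(facets))
  if (!is.null(items)) attr(out, "items") <- items
  out
}

participant_seed <- function(config, index) {
  as.integer((config$seed + 7919 * index) %% 2147483629L)
}

#' Generate one participant's node time series
#'
#' Draws correlated Gaussian node signals whose inter-node correlation
#' matrix is the participant's trait-modulated coupling matrix (see
#' [cohort_config()]). Runs are generated independently and concatenated.
#' Nonlinear pairs, if configured, replace the second node's signal with
#' the stated function of the first plus noise.
#'
#' @param record One row of the [generate_participants()] table.
#' @param config A [cohort_config()].
#' @param index Participant index used to derive a reproducible
#'   per-participant seed; defaults to the numeric suffix of
#'   `participant_id`.
#' @return A node x time numeric matrix (`n_nodes` rows, `n_runs *
#'   timepoints_per_run` columns) with node labels as row names.
#' @export
generate_time_series <- function(record, config, index = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(index)) {
    index <- suppressWarnings(as.integer(sub("^sub_", "", record$participant_id)))
    if (is.na(index)) index <- 1L
  }
  z <- (record[[config$effect_trait]] -
          config$trait_means[[config$effect_trait]]) /
    config$trait_sds[[config$effect_trait]]
  r <- coupling_matrix(config, z)
  ch <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(ch))
    stop_config("implied correlation matrix is not positive definite for ",
                "participant ", record$participant_id,
                " (trait z-score ", sprintf("%.2f", z), ")")
  set.seed(participant_seed(config, index))
  tp <- config$timepoints_per_run
  runs <- lapply(seq_len(config$n_runs), function(run) {
    g <- matrix(rnorm(tp * config$n_nodes), tp, config$n_nodes) %*% ch
    t(g) * config$noise_sd
  })
  values <- do.call(cbind, runs)
  rownames(values) <- config$node_labels
  for (nl in config$nonlinear_pairs) {
    a <- values[nl$pair[1], ]
    u <- (a - mean(a)) / sd(a)
    f <- switch(nl$form,
                quadratic = u^2,
                sinusoidal = sin(pi * u))
    f <- (f - mean(f)) / sd(f)
    values[nl$pair[2], ] <- config$noise_sd *
      (f + config$nonlinear_noise_sd * rnorm(length(f))) /
      sqrt(1 + config$nonlinear_noise_sd^2)
  }
  values
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper: participant records plus one node-time-series
#' matrix per participant, all reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with elements `participants` (data frame) and `series`
#'   (named list of node x time matrices).
#' @export
generate_cohort <- function(config) {
  participants <- generate_participants(config)
  series <- lapply(seq_len(nrow(participants)), function(i) {
    generate_time_series(participants[i, ], config, index = i)
  })
  names(series) <- participants$participant_id
  list(participants = participants, series = series)
}

#' Write a cohort to disk
#'
#' Writes `participants.csv` (header `participant_id,age,sex,N,E,O,A,C,`
#' `order,dutifulness,achievement_striving,self_discipline`) and one
#' tab-separated time-series file per participant under `timeseries/`
#' (first row node labels, then one row per timepoint). Files round-trip
#' losslessly through [read_participants()] and [read_time_series()].
#'
#' @param participants Data frame from [generate_participants()].
#' @param series Named list of node x time matrices, keyed by
#'   `participant_id`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(participants, series, dir) {
  if (nrow(participants) == 0 || length(series) == 0)
    stop_data("refusing to write an empty cohort")
  if (anyDuplicated(participants$participant_id))
    stop_data("duplicate participant_id in records")
  if (!setequal(names(series), participants$participant_id))
    stop_data("records and series are keyed inconsistently")
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  ppath <- file.path(dir, "participants.csv")
  write_participants(participants, ppath)
  tpaths <- vapply(participants$participant_id, function(id) {
    p <- file.path(dir, "timeseries", paste0(id, ".tsv"))
    write_time_series(series[[id]], p)
    p
  }, character(1))
  invisible(c(ppath, tpaths))
}
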