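# Simulated metric tables for scan-level tests: Gaussian graph-measure
# outcomes, with a chosen partial correlation planted between a trait and
# selected (node, metric) outcomes.

sim_participants <- function(n, seed = 1) {
  set.seed(seed)
  traits <- c("neuroticism", "extraversion", "openness", "agreeableness",
              "conscientiousness")
  df <- data.frame(participant_id = sprintf("sub_%04d", seq_len(n)),
                   age = sample(22:37, n, replace = TRUE),
                   sex = rbinom(n, 1, 0.5),
                   stringsAsFactors = FALSE)
  for (t in traits) df[[t]] <- rnorm(n, 30, 6)
  for (f in c("order", "dutifulness", "achievement_striving",
              "self_discipline"))
    df[[f]] <- 16 + 4 * (0.7 * scale(df$conscientiousness)[, 1] +
                           sqrt(1 - 0.49) * rnorm(n))
  df
}

# planted: character vector of outcome names "node.metric" receiving the
# effect; partial_r: target partial correlation with `trait`
sim_metric_tables <- function(participants, planted = character(0),
                              partial_r = 0, trait = "conscientiousness",
                              n_nodes = 15, seed = 1) {
  set.seed(seed)
  n <- nrow(participants)
  nodes <- c("left_FPN", "right_FPN", "DMN",
             sprintf("node_%02d", seq.int(4, n_nodes)))[seq_len(n_nodes)]
  mets <- c("strength", "clustering", "local_efficiency", "betweenness")
  z <- scale(participants[[trait]])[, 1]
  b <- if (partial_r > 0) partial_r / sqrt(1 - partial_r^2) else 0
  metrics <- do.call(rbind, lapply(nodes, function(nd) {
    row <- data.frame(participant_id = participants$participant_id,
                      node = nd, stringsAsFactors = FALSE)
    for (m in mets) {
      oc <- paste(nd, m, sep = ".")
      row[[m]] <- rnorm(n) + if (oc %in% planted) b * z else 0
    }
    row
  }))
  globals <- data.frame(participant_id = participants$participant_id,
                        global_strength = rnorm(n),
                        global_clustering = rnorm(n),
                        global_efficiency = rnorm(n),
                        stringsAsFactors = FALSE)
  list(metrics = metrics, globals = globals)
}
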