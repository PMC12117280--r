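# Shared fixtures: all synthetic, built in code at test time.

# Small complete-data trial for fast pipeline tests.
small_trial <- function(n = 120, seed = 1, moderation = 1, signal = 1,
                        missing_rate = 0) {
  generate_trial(generator_config(
    n_participants = n, seed = seed, missing_rate = missing_rate,
    outcome_model = default_outcome_model(moderation = moderation,
                                          signal = signal)))
}

# Random standardized feature matrix with an identity feature map.
random_features <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  attr(X, "feature_map") <- setNames(colnames(X), colnames(X))
  X
}

# Chi-square via the expected-count formulation, the independent oracle
# for the closed-form implementation.
chisq_expected_counts <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Brute-force AUC by concordant-pair counting.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) total <- total + sum(x > neg) + 0.5 * sum(x == neg)
  total / (length(pos) * length(neg))
}
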