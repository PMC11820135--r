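# Shared fixtures and independent oracle implementations.

fixture_env <- new.env(parent = emptyenv())

# One small decoder trained on a strong-contrast batch, built lazily and
# reused by controller / CLI tests.
get_trained_decoder <- function() {
  if (is.null(fixture_env$decoder)) {
    batch <- generate_epoch_batch(subject_profile(effect_size = 0.9,
                                                  seed = 31),
                                  n_per_class = 60)
    parts <- split_by_group(batch, "trial", 0.25, seed = 1)
    fixture_env$decoder <- mi_decoder(parts$train, val_epochs = parts$test,
                                      max_epochs = 40, patience = 15,
                                      seed = 2)
  }
  fixture_env$decoder
}

# Raw (un-normalized) feature stream of one class for controller sessions.
class_feature_stream <- function(label, n, effect_size = 0.9, seed = 77) {
  batch <- generate_epoch_batch(subject_profile(effect_size = effect_size,
                                                seed = seed),
                                n_per_class = n)
  feats <- featurize_epochs(batch, normalize = FALSE)
  idx <- which(batch$labels == label)[seq_len(n)]
  lapply(idx, function(i) feats[i, , ])
}

# --- independent metric oracles (direct formulas / pair counting) ---------

brute_accuracy <- function(truth, pred) mean(truth == pred)

brute_f1 <- function(truth, pred) {
  tp <- sum(truth == "fist" & pred == "fist")
  fp <- sum(truth == "rest" & pred == "fist")
  fn <- sum(truth == "fist" & pred == "rest")
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

brute_kappa <- function(truth, pred) {
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- sum(vapply(c("rest", "fist"), function(l)
    mean(truth == l) * mean(pred == l), 0))
  if (pe >= 1) 0 else (po - pe) / (1 - pe)
}

# AUC by exhaustive pair counting with half credit for ties.
brute_auc <- function(scores, truth) {
  pos <- scores[truth == "fist"]
  neg <- scores[truth == "rest"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force sliding-window count: enumerate starts directly.
brute_epoch_count <- function(T, length_s, overlap_s) {
  hop <- length_s - overlap_s
  n <- 0L
  s <- 0
  while (s + length_s <= T + 1e-9) {
    n <- n + 1L
    s <- n * hop
  }
  n
}
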