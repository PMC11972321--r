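# Independent oracles used across the suite. These never call the package
# routines they are checking.

# Entropy / conditional entropy / information gain by explicit
# contingency-table enumeration.
oracle_entropy <- function(y) {
  counts <- as.numeric(table(y))
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_cond_entropy <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  h <- 0
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    nx <- sum(row)
    if (nx == 0) next
    p <- row / nx
    p <- p[p > 0]
    h <- h + (nx / n) * (-sum(p * log2(p)))
  }
  h
}

oracle_ig <- function(x, y) oracle_entropy(y) - oracle_cond_entropy(x, y)

# AUC as the Mann-Whitney concordant-pair fraction (ties count 1/2),
# by brute-force pair enumeration.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force confusion tally and rates.
oracle_counts <- function(yt, yp) {
  c(TP = sum(yt == 1 & yp == 1), TN = sum(yt == 0 & yp == 0),
    FP = sum(yt == 0 & yp == 1), FN = sum(yt == 1 & yp == 0))
}

# Shared expensive fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

# Separable-data classifier at the full calibration budget.
get_sep_fit <- function() {
  if (is.null(.fixture_cache$sep)) {
    d <- gen_separable(400, margin = 1, seed = 5)
    sp <- stratified_split(d$y, 0.8, seed = 5)
    model <- train_with_pcso(network_spec(2), d$X[sp$train, ],
                             d$y[sp$train], pop_size = 30L,
                             max_iters = 150L, seed = 5)
    .fixture_cache$sep <- list(data = d, split = sp, model = model)
  }
  .fixture_cache$sep
}

# U-Net trained 20 epochs on 50 phantoms; 10 held-out pairs.
get_trained_unet <- function() {
  if (is.null(.fixture_cache$unet)) {
    pairs <- gen_phantoms(60, size = 64, seed = 11, noise_sigma = 0.05)
    model <- train_unet(unet_spec(), pairs[1:50], epochs = 20L, lr = 1e-3,
                        batch_size = 8L, seed = 1)
    .fixture_cache$unet <- list(model = model, train = pairs[1:50],
                                test = pairs[51:60])
  }
  .fixture_cache$unet
}
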