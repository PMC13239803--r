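# Shared fixtures, built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(...) {
  defaults <- list(N = 240, M = 3, features_m = rep(200L, 3), K_true = 4,
                   snr = 5, n_sites = 8, n_scanners = 3, seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# A small fitted pipeline reused by several test files.
small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    ds <- generate_dataset(small_config())
    sp <- grouped_split(ds$pheno$site, seed = 3)
    model <- suppressWarnings(
      fit_fusion(ds, sp, K = 4,
                 control = fusion_control(epochs = 300, patience = 30,
                                          seed = 1)))
    .fixture_env$fit <- list(ds = ds, sp = sp, model = model)
  }
  .fixture_env$fit
}

# Brute-force AUROC: exhaustive concordant/discordant pair counting.
pair_count_auroc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
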