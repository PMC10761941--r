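# Shared fixtures. Heavy objects (the full desk-scale studies used by the
# acceptance suite) are built once per session and memoised; light fixtures
# are rebuilt on demand.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Full desk-scale study (generalization + memorization networks, quilt
# curves, ablation) for a given seed.
get_study <- function(seed) {
  cached(paste0("study_", seed), run_study(seed = seed))
}

# A small trained tagger on an easy 3-category synthetic task, shared by
# network/probe tests.
get_toy_fit <- function() {
  cached("toy_fit", {
    sc <- synth_config(categories = c("music", "water", "barks"),
                       music_categories = "music",
                       speech_categories = character(0),
                       clips_per_category = 8, mixed_fraction = 0,
                       overlay_fraction = 0, seed = 11L)
    ds <- generate_dataset(sc)
    fe <- frontend_config()
    x <- stack_spectrograms(lapply(ds$clips, to_log_mel, config = fe),
                            time_pool = 16L)
    y <- t(vapply(split_labels(ds$manifest$labels),
                  function(l) as.numeric(sc$categories %in% l),
                  numeric(3)))
    colnames(y) <- sc$categories
    arch <- arch_config(channels = c(4, 8, 8, 16), fc_hidden = 16,
                        n_categories = 3)
    model <- build_tagger(arch, seed = 3L)
    tc <- train_config(epochs = 50, batch_size = 4, warmup_epochs = 15,
                       seed = 3L)
    model <- train_tagger(model, x, y, tc)
    list(model = model, x = x, y = y, dataset = ds, frontend = fe,
         synth = sc)
  })
}

# A linearly separable two-category toy: spectrogram-like inputs whose
# classes occupy disjoint mel bands.
get_separable_fit <- function() {
  cached("separable_fit", {
    set.seed(21)
    n <- 16
    x <- array(stats::rnorm(32 * 20 * n, sd = 0.1), c(32, 20, n))
    y <- cbind(a = rep(c(1, 0), each = n / 2),
               b = rep(c(0, 1), each = n / 2))
    for (i in seq_len(n)) {
      rows <- if (y[i, "a"] == 1) 5:12 else 20:27
      x[rows, , i] <- x[rows, , i] + 2
    }
    arch <- arch_config(channels = c(4, 8), pool = list(c(2, 2)),
                        fc_hidden = 8, n_categories = 2, n_mels = 32)
    model <- build_tagger(arch, seed = 1L)
    tc <- train_config(epochs = 60, batch_size = 4, warmup_epochs = 18,
                       seed = 1L)
    model <- train_tagger(model, x, y, tc)
    list(model = model, x = x, y = y, config = tc, arch = arch)
  })
}

# Envelope autocorrelation computed independently of the package helpers
# (plain matrix arithmetic), used as the oracle for generator structure
# checks.
oracle_env_autocorr <- function(samples, sr, frame_s, lag_s) {
  fn <- round(frame_s * sr)
  nf <- floor(length(samples) / fn)
  m <- matrix(samples[seq_len(nf * fn)], nrow = fn)
  env <- sqrt(colMeans(m^2))
  lag <- round(lag_s / frame_s)
  stats::cor(env[seq_len(nf - lag)], env[(lag + 1):nf])
}
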