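# Shared fixtures, built once per test session and cached, so several test
# files can reuse the expensive synthetic feature matrices.

.fixture_cache <- new.env(parent = emptyenv())

cached_features <- function(key, n_per_class, seed, null_gap = FALSE) {
  if (!exists(key, envir = .fixture_cache)) {
    cohort <- if (null_gap)
      generate_cohort(n_per_class, spec_depr = preset_spec("null"),
                      spec_neg = preset_spec("null"), seed = seed)
    else generate_cohort(n_per_class, seed = seed)
    assign(key, build_feature_matrix(cohort), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 100 epochs per class under the default class presets
features_small <- function() cached_features("f100", 100L, 101L)

# the full-size default cohort (510 per class) and its null-gap twin
features_full <- function() cached_features("f510", 510L, 42L)
features_nullgap <- function() cached_features("null510", 510L, 43L, null_gap = TRUE)

# Pure-R brute-force sample-entropy oracle: O(N^2) double loop over
# templates, independent of the package's compiled counting path.
sampen_oracle_counts <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

sampen_oracle <- function(x, m = 2, r_factor = 0.2) {
  cnt <- sampen_oracle_counts(x, m, r_factor * sd(x))
  -log(cnt[["A"]] / cnt[["B"]])
}

# Seeded standard epoch with arbitrary content for I/O and feature tests.
toy_epoch <- function(seed = 1, spec = preset_spec("depression"))
  generate_epoch(spec, seed)
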