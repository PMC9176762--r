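# Shared fixtures, cached per session so the full-scale registry is only
# generated once across test files.
fixture_env <- new.env(parent = emptyenv())

full_fixture <- function(seed = 1L) {
  key <- paste0("fix", seed)
  if (is.null(fixture_env[[key]])) {
    rec <- generate_registry(registry_config(), seed = seed)
    fixture_env[[key]] <- apply_exclusions(rec)
  }
  fixture_env[[key]]
}

# A small registry CSV written to a temp file, built in code.
write_toy_registry <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# patterns (midranked ties), the brute-force oracle for small n.
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  allW <- vapply(0:(2^n - 1), function(m) {
    sum(rk[bitwAnd(m, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  min(1, 2 * min(mean(allW <= W + 1e-9), mean(allW >= W - 1e-9)))
}

# Threshold sets with a never-modal middle category in every item: the
# designed disorder scenario used by the detection and repair tests.
disordered_thresholds <- function() {
  list(a = c(1, -1), b = c(-0.5, 1.5, 0.5), c = c(0.8, -0.8))
}

# The adjacent-merge remedy for disordered_thresholds().
disorder_remedy_map <- function() {
  collapse_map(a = c(0L, 1L, 1L), b = c(0L, 1L, 2L, 2L), c = c(0L, 1L, 1L))
}
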