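# Deterministic substream seeds: mix a root seed with integer indices so that
# replicate r (and any deeper index) always maps to the same 31-bit seed,
# independent of how many cells or streams other replicates consume.
mix_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + (as.double(k) + 1) * 668265263) %% 2147483647
  }
  as.integer(s)
}

# summary.lm warns on exactly collinear (noise-free) fits; such inputs are
# legitimate here (closed-form series), so that warning is muffled.
quiet_lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

is_power_of_two <- function(x) {
  is.finite(x) & x > 0 & abs(log2(x) - round(log2(x))) < 1e-9
}

# Largest-remainder apportionment of n items over fractions (sums to n).
apportion_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}
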