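# Internal helpers shared across modules.

# Deterministic sub-seed derivation: a fixed LCG step over a master seed and
# a counter, so per-patient / per-stage draws are reproducible independently
# of evaluation order. Stays inside 32-bit integer range.
derive_seed <- function(master, counter) {
  m <- 2147483647
  x <- (as.double(master) %% m) + 1
  y <- (x * 48271 + as.double(counter) * 69621) %% (m - 1)
  as.integer(y + 1)
}

# messages routed through one place so verbosity can be controlled centrally
smm_log <- function(..., verbose = getOption("smmsubtype.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
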