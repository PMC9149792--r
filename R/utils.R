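# RNG bookkeeping: functions that take an explicit seed save and restore the
# caller's stream so simulation code stays composable.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

# Counter-based per-run seed derivation: independent, replayable, < 2^31.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 48271 + counter * 16807) %%
               2147483647)
}

# Minor-allele carrier count per variant: samples carrying at least one copy
# of the minor allele (non-missing calls only).
minor_carrier_counts <- function(panel) {
  calls <- panel$calls
  ploidy <- panel$ploidy
  alt_count <- colSums(calls, na.rm = TRUE)
  n_called <- colSums(!is.na(calls))
  total <- ploidy * n_called
  alt_is_minor <- alt_count <= total - alt_count
  carriers_alt <- colSums(calls > 0, na.rm = TRUE)
  carriers_ref <- colSums(calls < ploidy, na.rm = TRUE)
  ifelse(alt_is_minor, carriers_alt, carriers_ref)
}
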