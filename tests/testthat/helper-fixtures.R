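# Shared fixtures and independent oracles used across test files.

# closed-form ordinary least squares via the normal equations, independent
# of stats::lm
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# per-base rule application, character by character, independent of the
# vectorised implementation
bisulfite_oracle <- function(seq, cpg_methylated = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  out <- chars
  for (i in seq_along(chars)) {
    if (chars[i] == "C") {
      protected <- cpg_methylated && i < length(chars) && chars[i + 1] == "G"
      if (!protected) out[i] <- "T"
    }
  }
  paste(out, collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# minimal wells table for hand-built plates
make_wells <- function(sample_id, role, channel, ct, known_amount = NA_real_,
                       replicate = 1L, well_id = NULL) {
  n <- max(lengths(list(sample_id, role, channel, ct)))
  tibble::tibble(
    well_id = if (is.null(well_id)) sprintf("W%02d", seq_len(n)) else well_id,
    sample_id = sample_id, role = role, channel = channel, ct = ct,
    known_amount = known_amount, replicate = replicate
  )
}

# a small fully-specified plate: standards, indicators, one gDNA/BS pair
toy_plate <- function(ct_noise_sd = 0, seed = 99) {
  sim <- simulate_run(simulation_config(seed = seed, n_samples = 2,
                                        ct_noise_sd = ct_noise_sd))
  sim
}
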