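# shared helpers: tiny spectra/libraries built in code

# spectrum with given intensities at given integer masses, zeros elsewhere
spec_at <- function(masses, intensities, mz_min = 85L, mz_max = 500L) {
  ints <- numeric(mz_max - mz_min + 1L)
  ints[masses - mz_min + 1L] <- intensities
  mass_spectrum(ints, mz_min, mz_max)
}

# textbook two-pass Pearson correlation (independent oracle for pearson_doc)
pearson_two_pass <- function(u, v) {
  mu <- sum(u) / length(u)
  mv <- sum(v) / length(v)
  num <- sum((u - mu) * (v - mv))
  num / sqrt(sum((u - mu)^2) * sum((v - mv)^2))
}

# library of entries with identical spectra (distinct signature mass each)
# at the given retention times
grid_library <- function(rts, mz_min = 85L, mz_max = 500L) {
  lapply(seq_along(rts), function(i) {
    reference_entry(sprintf("cmp_%03d", i), rts[i],
                    spec_at(c(100L, 200L, 250L + (i %% 200L)), c(100, 50, 40),
                            mz_min, mz_max))
  })
}
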