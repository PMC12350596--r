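# Shared fixtures. Built once per test process; everything is generated in
# code, no stored data.

# default spec (copula calibration runs once here)
default_spec <- cohort_spec()

# spec with wide truncation bounds, for distribution-recovery checks where
# the physical bounds would otherwise clip the normal tails
wide_spec <- function(n_low = 96, n_high = 22) {
  gp <- default_group_params()
  gp$lo <- c(-500, -500, -500, -500, -5000, -5000, 1e-6, -1, -500)
  gp$hi <- c(1500, 1500, 1500, 99.9, 20000, 20000, 3, 3, 1500)
  cohort_spec(n_low = n_low, n_high = n_high, group_params = gp)
}

# small noiseless phantom for measurement-chain tests (2 mm spacing keeps it
# fast); liver phase means imply IWR = (63.7 - 35.6)/63.7 * 100
small_phantom_spec <- function(noise_sd = 0, seed = 1L) {
  phantom_spec(grid = c(96, 96, 48), spacing = c(2, 2, 2),
               noise_sd = noise_sd, seed = seed)
}

# six-subject two-reader fixture with a hand-computable two-way ANOVA
icc_fixture <- function() {
  list(r1 = c(10, 12, 14, 16, 18, 20),
       r2 = c(11, 12, 13, 17, 17, 21))
}
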