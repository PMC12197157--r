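# Shared fixtures, built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

# The default study cohort: 40 samples/group, healthy vs blackhearted,
# full 400-1000 nm grid, 10% CV, 1% measurement noise, seed 7.
default_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(cohort_spec(n_per_group = 40, seed = 7))
  .fixtures$cohort
}

healthy_mean <- function() {
  if (is.null(.fixtures$healthy))
    .fixtures$healthy <- generate_group_spectrum("healthy")
  .fixtures$healthy
}

blackhearted_mean <- function() {
  if (is.null(.fixtures$bh))
    .fixtures$bh <- generate_group_spectrum("blackhearted")
  .fixtures$bh
}

# binomial standard error of an escape fraction
mc_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
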