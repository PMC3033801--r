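# Simulation studies shared by several acceptance checks; computed once per
# test run and cached. Scales: the null study follows the prescribed design
# (500 replicates of a 15-gene / 159-SNP LD-free null pathway, 300 cases +
# 300 controls, 200 permutations); the power study runs pattern 1 at f = 1
# and the published sample size with 100 replicates x 100 permutations (the
# package's desk scale, see the methods vignette).

study_cache <- new.env(parent = emptyenv())

get_null_study <- function() {
  if (is.null(study_cache$null))
    study_cache$null <- type_one_error_study(
      R = 500L, B = 200L, n_cases = 300L, n_controls = 300L,
      pattern = "pattern1", ld = list(model = "independent"), seed = 101L)
  study_cache$null
}

get_power_study <- function() {
  if (is.null(study_cache$power))
    study_cache$power <- power_study(
      pattern = "pattern1", f = 1, R = 100L, B = 100L,
      n_cases = 1350L, n_controls = 1350L, seed = 202L)
  study_cache$power
}
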