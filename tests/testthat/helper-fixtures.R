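# Shared fixtures built in code. The GAN bundle is trained once per test
# run (small cohort, short schedule) and memoized for the unit tests;
# the full-schedule bundle lives in the acceptance tests only.

small_cohort <- function(n = 80L, seed = 1L) {
  spec <- default_spec()
  spec$n <- as.integer(n)
  sample_cohort(spec, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

small_gan <- function() {
  if (is.null(.fixture_env$gan)) {
    co <- small_cohort(100L, seed = 3L)
    .fixture_env$gan <- suppressWarnings(
      gan_fit(co, gan_config(epochs = 60L, seed = 7L)))
    .fixture_env$gan_cohort <- co
  }
  .fixture_env$gan
}

# two-row cohort template for hand-built records
manual_cohort <- function(age, gender, site, metastatic = 1L,
                          bone_mets = 0L, btcp = 0L, neuropathic = 0L,
                          ecog = 2L, med_gt60 = 1L, n_televisits = 1L) {
  n <- max(lengths(list(age, gender, site)))
  df <- data.frame(
    patient_id = seq_len(n),
    age = as.integer(rep_len(age, n)),
    gender = factor(rep_len(gender, n), levels = c("female", "male")),
    site = factor(rep_len(site, n),
                  levels = levels(small_cohort(2L)$site)),
    metastatic = as.integer(rep_len(metastatic, n)),
    bone_mets = as.integer(rep_len(bone_mets, n)),
    btcp = as.integer(rep_len(btcp, n)),
    neuropathic = as.integer(rep_len(neuropathic, n)),
    ecog = as.integer(rep_len(ecog, n)),
    med_gt60 = as.integer(rep_len(med_gt60, n)),
    n_televisits = as.integer(rep_len(n_televisits, n))
  )
  df$outcome <- factor(ifelse(df$n_televisits > 1, "more", "one"),
                       levels = c("one", "more"))
  class(df) <- c("patient_cohort", "data.frame")
  df
}
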