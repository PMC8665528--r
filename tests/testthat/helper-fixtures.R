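# Small in-code fixtures shared across the test files.

# A tiny two-subgroup dataset with deterministic covariates and survival.
tiny_two_subgroups <- function(n = 12, p = 4, seed = 99) {
  set.seed(seed)
  make_sg <- function(id) {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("gene", seq_len(p))))
    time <- round(rexp(n, 0.3) + 0.05, 3)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) < 2) event[1:2] <- 1
    subgroup_dataset(X, time, event, subgroup_id = id)
  }
  multi_subgroup_data(list(make_sg("A"), make_sg("B")))
}

# Write a multi_subgroup_data object to temp CSVs; returns the two paths.
write_tmp_tables <- function(data) {
  sp <- tempfile(fileext = ".csv")
  cp <- tempfile(fileext = ".csv")
  write_multi_subgroup(data, sp, cp)
  list(survival = sp, covariates = cp)
}
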