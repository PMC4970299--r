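# Small named matrices in the shapes the scans expect.

fm <- function(values, n_features, n_samples, prefix = "f",
               samples = paste0("s", seq_len(n_samples))) {
  matrix(values, n_features, n_samples,
         dimnames = list(paste0(prefix, seq_len(n_features)), samples))
}

rand_study <- function(n = 30L, n_cpg = 5L, n_snp = 3L, n_env = 2L,
                       n_cvrt = 1L, seed = 42L) {
  set.seed(seed)
  list(
    M = fm(runif(n_cpg * n), n_cpg, n, "cg"),
    G = fm(sample(0:2, n_snp * n, replace = TRUE) * 1.0, n_snp, n, "rs"),
    E = fm(rnorm(n_env * n), n_env, n, "env"),
    cvrt = if (n_cvrt > 0L) fm(rnorm(n_cvrt * n), n_cvrt, n, "cv")
  )
}

# join fast-path records to an oracle sweep on the shared key columns
match_oracle <- function(fast, oracle) {
  keys <- intersect(c("outcome_id", "predictor_id", "env_id"),
                    names(fast))
  i <- match(do.call(paste, fast[keys]), do.call(paste, oracle[keys]))
  stopifnot(!anyNA(i))
  oracle[i, ]
}

max_rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(b), .Machine$double.eps))
}
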