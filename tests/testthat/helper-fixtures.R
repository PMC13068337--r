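# Shared fixtures, built in code at test time.

# small abundance table with explicit values
tiny_table <- function(m, modality = "mGx", scale = "relative") {
  rownames(m) <- rownames(m) %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("f%d", seq_len(ncol(m)))
  df <- tibble::tibble(sample_id = rownames(m))
  df <- dplyr::bind_cols(df, tibble::as_tibble(as.data.frame(m)))
  abundance_table(df, modality = modality, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# metadata for n patients with v samples each and given diagnoses
tiny_metadata <- function(diagnoses, visits = 2) {
  n <- length(diagnoses)
  pats <- sprintf("P%02d", seq_len(n))
  tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n * visits)),
    patient_id = rep(pats, each = visits),
    diagnosis = rep(diagnoses, each = visits),
    visit = rep(seq_len(visits), n))
}

# small synthetic cohort for fast model tests
small_sim <- function(seed = 1, ...) {
  simulate_multiomics(sim_config(
    n_patients = 12, samples_per_patient = 3,
    n_features = c(mGx = 30, mBx = 15),
    sparsity = c(mGx = 0.2, mBx = 0.1),
    n_signal_outputs = 4, signal_support = 3, signal_strength = 8,
    n_class_features = c(mGx = 4, mBx = 4),
    seed = seed, ...))
}

# paired dataset whose outputs are an exact linear map of the CLR inputs:
# latent rows are centered so CLR(input) equals the latent exactly
noiseless_linear_paired <- function(n = 60, p = 15, q = 5, seed = 42) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  z <- z - rowMeans(z)
  B <- matrix(rnorm(p * q, sd = 0.6), p, q)
  y <- z %*% B
  Xin <- exp(z) / rowSums(exp(z))
  Yout <- exp(y) / rowSums(exp(y))
  rownames(Xin) <- rownames(Yout) <- sprintf("s%03d", seq_len(n))
  colnames(Xin) <- sprintf("g%02d", seq_len(p))
  colnames(Yout) <- sprintf("b%02d", seq_len(q))
  meta <- tibble::tibble(sample_id = rownames(Xin),
                         patient_id = sprintf("P%02d", rep(seq_len(n / 2), each = 2)),
                         diagnosis = rep(c("HC", "UC"), length.out = n / 2)[rep(seq_len(n / 2), each = 2)],
                         visit = rep(1:2, n / 2))
  make_paired(tiny_table(Xin, "mGx"), tiny_table(Yout, "mBx"), meta)
}

# heavy shared fixture for the end-to-end recovery analyses: computed once
# per test run and reused (default cohort, 10 patient-level splits,
# elastic-net benchmark)
.recovery_cache <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (is.null(.recovery_cache$value)) {
    sim <- simulate_multiomics(sim_config(seed = 0))
    paired <- paired_from_sim(sim)
    plans <- make_splits(sim$metadata, n_splits = 10)
    bench <- run_benchmark(paired, plans, models = "elastic_net", top_k = 10)
    .recovery_cache$value <- list(sim = sim, paired = paired, plans = plans,
                                  bench = bench)
  }
  .recovery_cache$value
}
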