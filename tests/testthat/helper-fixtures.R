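# Shared fixtures, built in code.

default_acq <- function(N_max = 1e4, ...) acquisition_model(N_max = N_max, ...)

# small simulated tetramer data set under the standard study conditions
small_tetramer_table <- function(n_oligo = 2000, N_max = 1e4, seed = 42, ...) {
  simulate_dataset(oligomer_spec(n = 4, l = 5, n_oligomers = n_oligo, ...),
                   default_acq(N_max), seed = seed)
}

# independent scalar re-implementations of the CRLB formulas (oracles)
oracle_tau <- function(N, b, a, s) 2 * pi * b * (s^2 + a^2 / 12) / (N * a^2)
oracle_dN <- function(N, b, a = 100, s = 160) {
  t <- oracle_tau(N, b, a, s)
  sqrt(N * (1 + 4 * t + sqrt(t / (14 * (1 + 2 * t)))))
}
oracle_dx <- function(N, b, a = 100, s = 160) {
  t <- oracle_tau(N, 2 * b, a, s)
  sqrt((s^2 + a^2 / 12) / N * (1 + 4 * t + sqrt(2 * t / (1 + 4 * t))))
}

# single-linkage components via hclust (independent clustering oracle)
oracle_threshold_groups <- function(x, y, thr) {
  if (length(x) == 1) return(1L)
  cutree(hclust(dist(cbind(x, y)), method = "single"), h = thr)
}

derive_seed_for_test <- function(seed, i) oligosizer:::derive_seed(seed, i)

# partitions equal up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) && all(outer(a, a, "==") == outer(b, b, "=="))
}
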