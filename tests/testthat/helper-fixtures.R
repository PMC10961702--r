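# shared helpers: scaled-down generator configs and random model sampling

# small config for fast unit tests; higher prevalences so every class is
# represented at modest n
small_config <- function(n_chemicals = 200L, n_clusters = 8L, ...) {
  generator_config(
    n_chemicals = n_chemicals,
    prevalence = c(antagonist = 0.20, agonist = 0.08, both = 0.02),
    n_clusters = n_clusters,
    agonist_cluster_fraction = 0.25,
    fingerprint_length = 128L,
    ...
  )
}

# random subset-model names, optionally restricted to the first `n_assays`
# bit positions
rand_models <- function(n, n_assays = 14L, min_size = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    bits <- integer(14L)
    k <- sample(min_size:n_assays, 1L)
    bits[sample.int(n_assays, k)] <- 1L
    out <- unique(c(out, paste0("A", paste(bits, collapse = ""))))
    out <- setdiff(out, "A11111111111111")  # reserved for the reference
  }
  out[seq_len(n)]
}

# independent brute-force confusion tabulation from two 0/1 vectors
brute_confusion <- function(pred, ref) {
  tab <- table(factor(pred, levels = 0:1), factor(ref, levels = 0:1))
  list(tp = tab["1", "1"], fp = tab["1", "0"],
       tn = tab["0", "0"], fn = tab["0", "1"])
}
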