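# shared test helpers: deterministic guides, site signatures, tiny oracles

random_guide <- function(seed, len_a = 9L, len_b = 9L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "U")
  guide_pair(paste(sample(bases, len_a, TRUE), collapse = ""),
             paste(sample(bases, len_b, TRUE), collapse = ""))
}

# canonical serialization of a site list for set comparisons
sites_sig <- function(sites) {
  sort(vapply(sites, function(s)
    paste(s$start, s$end, s$gap, s$arrangement,
          paste(s$mismatches_a, collapse = "."),
          paste(s$mismatches_b, collapse = "."), sep = "|"), ""))
}

# footprint-only signature (ignores region labelling)
footprint_sig <- function(sites) {
  sort(vapply(sites, function(s)
    paste(s$start, s$end, s$gap, sep = "|"), ""))
}

# deterministic per-seed fixture parameters for the recovery sweeps
sweep_params <- function(seed) {
  set.seed(seed * 1009L + 17L)
  list(edge_len = sample(8:12, 1L), loop_len = sample(8:12, 1L),
       spacer_len = sample(8:12, 1L), n_units = sample(5:15, 1L))
}
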