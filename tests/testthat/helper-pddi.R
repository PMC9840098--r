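# shared fixtures, built in code

test_group <- pddi_group_params("test")

# a small two-institution keypair reused across crypto tests
fresh_keys <- function(ids = c("A", "B"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pddi_keygen(test_group, ids)
}

decrypt_all <- function(ct, kg, bound = ct$n_institutions) {
  partials <- lapply(kg$shares, function(s) pddi_partial_decrypt(ct, s))
  pddi_combine_and_decode(ct, partials, bound = bound)
}

# a deterministic tiny linked pair for pipeline tests
tiny_pair <- function(n_screening = 60, n_registry = 150, n_common = 20,
                      plan = zero_error_plan(), seed = 42) {
  build_linked_pair(dataset_spec(n_screening, n_registry, n_common,
                                 plan = plan, seed = seed))
}

# brute-force multiset-free intersection of compressed keys across datasets
plaintext_intersection <- function(datasets, combo) {
  keysets <- lapply(datasets, function(d) unique(make_key(d, combo)))
  Reduce(intersect, keysets)
}

# link ids of a session result, regrouped per key for oracle comparison
session_group_count <- function(sess) length(unique(sess$result$link_id))
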