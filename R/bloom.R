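# Bloom-filter encoding of compressed key sets. The elementwise integer sum
# of all institutions' filters reveals, at each position, how many
# institutions set that bit; a key held by everyone has every one of its k
# positions equal to the institution count.

#' Bloom filter parameters
#'
#' @param m_bits filter length in bits.
#' @param k_hashes number of hash positions per key, at least 1 and at most
#'   `m_bits`.
#' @param salt session salt mixed into the position hashes. All institutions
#'   share it and it is withheld from the server, so the server cannot mount
#'   a dictionary attack on filter positions.
#' @return A `pddi_bloom_params` list.
#' @export
bloom_params <- function(m_bits, k_hashes, salt) {
  m_bits <- as.integer(m_bits)
  k_hashes <- as.integer(k_hashes)
  if (k_hashes < 1 || m_bits < k_hashes)
    stop("need k_hashes >= 1 and m_bits >= k_hashes")
  structure(list(m_bits = m_bits, k_hashes = k_hashes,
                 salt = as.character(salt)),
            class = "pddi_bloom_params")
}

#' Size a Bloom filter for a target false-positive probability
#'
#' Classic sizing: `m = ceil(-n ln(fpr) / ln(2)^2)` bits and
#' `k = round(m/n ln 2)` hashes give per-key false-positive probability
#' about `fpr` at capacity `n`. The default `1e-9` makes Bloom collisions
#' negligible next to the identifier-error effects under study, so protocol
#' output coincides with exact set intersection in practice.
#'
#' @param capacity largest declared key-set size among the institutions
#'   (all institutions use one shared shape so filters can be summed).
#' @param fpr target per-key false-positive probability.
#' @param salt session salt; a fresh random salt by default.
#' @return A `pddi_bloom_params` list.
#' @export
bloom_dimension <- function(capacity, fpr = 1e-9, salt = rng_hex(16)) {
  capacity <- max(1L, as.integer(capacity))
  m <- as.integer(ceiling(-capacity * log(fpr) / log(2)^2))
  k <- max(1L, as.integer(round(m / capacity * log(2))))
  bloom_params(m, k, salt)
}

#' Bloom positions of compressed keys
#'
#' Double hashing: positions `h1 + j * h2 (mod m)` for `j = 0..k-1`, with
#' `h1`, `h2` taken from disjoint 48-bit slices of `SHA-256(key:salt)`.
#' Deterministic in `(key, params)`.
#'
#' @param keys character vector of compressed keys (hex digests).
#' @param params a [bloom_params()] object.
#' @return integer matrix with `k_hashes` rows and one column per key;
#'   0-based positions in `[0, m_bits)`.
#' @export
bloom_positions <- function(keys, params) {
  stopifnot(inherits(params, "pddi_bloom_params"))
  h <- .sha256_hex(paste0(keys, ":", params$salt))
  m <- params$m_bits
  h1 <- hex_to_double(substr(h, 1L, 12L)) %% m
  h2 <- hex_to_double(substr(h, 13L, 24L)) %% m
  h2[h2 == 0] <- 1
  j <- seq_len(params$k_hashes) - 1
  pos <- outer(j, h2) + rep(h1, each = params$k_hashes)
  matrix(as.integer(pos %% m), nrow = params$k_hashes)
}

#' Build an institution's plain Bloom filter
#'
#' Sets the bit at every position of every key. Membership of each inserted
#' key is always reported (no false negatives); non-members collide with
#' probability controlled by [bloom_dimension()].
#'
#' @param keys compressed keys (deduplicated internally).
#' @param params a [bloom_params()] object.
#' @return A `pddi_bloom`: integer 0/1 vector `bits` plus `params`.
#' @export
build_filter <- function(keys, params) {
  stopifnot(inherits(params, "pddi_bloom_params"))
  bits <- integer(params$m_bits)
  keys <- unique(keys)
  if (length(keys) > 0) {
    pos <- bloom_positions(keys, params)
    bits[unique(as.integer(pos)) + 1L] <- 1L
  }
  structure(list(bits = bits, params = params), class = "pddi_bloom")
}

#' @export
print.pddi_bloom <- function(x, ...) {
  cat(sprintf("<Bloom filter: m = %d bits, k = %d, popcount = %d>\n",
              x$params$m_bits, x$params$k_hashes, sum(x$bits)))
  invisible(x)
}

#' Extract the intersection from a summed filter
#'
#' Given the decoded elementwise sum of all institutions' filters, returns
#' exactly those of the caller's own keys whose every Bloom position was set
#' by all `n_institutions` parties.
#'
#' @param counts integer vector of per-position counts (the decrypted summed
#'   filter).
#' @param own_keys the caller's compressed keys.
#' @param params the shared [bloom_params()].
#' @param n_institutions number of participating institutions.
#' @return the subset of `own_keys` present at every institution (up to the
#'   Bloom false-positive probability).
#' @export
intersect_mask <- function(counts, own_keys, params, n_institutions) {
  stopifnot(inherits(params, "pddi_bloom_params"),
            length(counts) == params$m_bits)
  if (any(counts > n_institutions))
    stop("corrupted transcript: summed count exceeds institution count")
  if (length(own_keys) == 0) return(character(0))
  pos <- bloom_positions(own_keys, params)
  hit <- matrix(counts[pos + 1L] == n_institutions, nrow = nrow(pos))
  own_keys[colSums(hit) == nrow(pos)]
}
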