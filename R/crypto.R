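# Lifted (exponential) ElGamal over a Schnorr group with n-of-n additive
# key sharing. Messages are the tiny per-position Bloom counts (<= number of
# institutions), so discrete-log decoding is an exact table lookup.

# RFC 3526 group 14: 2048-bit safe prime, generator 4 generates the order-q
# subgroup of quadratic residues, q = (p - 1) / 2 prime (2047 bits).
RFC3526_P2048 <- paste0(
  "ffffffffffffffffc90fdaa22168c234c4c6628b80dc1cd129024e088a67cc74",
  "020bbea63b139b22514a08798e3404ddef9519b3cd3a431b302b0a6df25f1437",
  "4fe1356d6d51c245e485b576625e7ec6f44c42e9a637ed6b0bff5cb6f406b7ed",
  "ee386bfb5a899fa5ae9f24117c4b1fe649286651ece45b3dc2007cb8a163bf05",
  "98da48361c55d39a69163fa8fd24cf5f83655d23dca3ad961c62f356208552bb",
  "9ed529077096966d670c354e4abc9804f1746c08ca18217c32905e462e36ce3b",
  "e39e772c180e86039b2783a2ec07a28fb5c55df06f4c52c9de2bcbf695581718",
  "3995497cea956ae515d2261898fa051015728e5a8aacaa68ffffffffffffffff")

#' Cryptographic group parameters
#'
#' A Schnorr group (prime-order subgroup of the multiplicative group modulo a
#' safe prime) over which the additively homomorphic cryptosystem operates.
#' `"test"` mode uses a deliberately tiny 31-bit group so that large filter
#' vectors encrypt in milliseconds; it offers no security and is intended for
#' unit tests and simulations. `"production"` mode uses the 2048-bit MODP
#' group of RFC 3526 (subgroup order 2047 bits).
#'
#' @param mode `"test"` or `"production"`.
#' @return An object of class `pddi_group`: list with hex fields `p`
#'   (modulus), `q` (subgroup order), `g` (generator of the order-q
#'   subgroup), and `mode`.
#' @examples
#' gp <- pddi_group_params("test")
#' @export
pddi_group_params <- function(mode = c("test", "production")) {
  mode <- match.arg(mode)
  if (mode == "test") {
    params <- list(p = "7fffffbb", q = "3fffffdd", g = "4", mode = mode)
  } else {
    p <- RFC3526_P2048
    params <- list(p = p, q = halve_hex(.bn_sub(p, "1")), g = "4",
                   mode = mode)
  }
  class(params) <- "pddi_group"
  stopifnot(.bn_modexp(params$g, params$q, params$p) == "1",
            params$g != "1")
  if (mode == "production" && .bn_nbits(params$q) < 224)
    stop("production subgroup order must have >= 224 bits")
  params
}

#' @export
print.pddi_group <- function(x, ...) {
  cat(sprintf("ElGamal group (%s mode): |p| = %d bits, |q| = %d bits\n",
              x$mode, .bn_nbits(x$p), .bn_nbits(x$q)))
  invisible(x)
}

# uniform scalar(s) in [1, q - 1]; test mode draws from the seedable R RNG,
# production mode from the OS entropy pool
rand_scalar <- function(params, n = 1L) {
  if (params$mode == "test") {
    q <- strtoi(params$q, 16L)
    int_to_hex(sample.int(q - 1L, n, replace = TRUE))
  } else {
    nb <- ceiling(.bn_nbits(params$q) / 8) + 8L
    q1 <- .bn_sub(params$q, "1")
    vapply(seq_len(n), function(i) {
      con <- file("/dev/urandom", "rb", raw = TRUE)
      on.exit(close(con))
      bytes <- readBin(con, "raw", nb)
      x <- .bn_mod(paste(sprintf("%02x", as.integer(bytes)), collapse = ""),
                   q1)
      .bn_addmod(x, "1", params$q)
    }, "")
  }
}

# table of g^0 .. g^bound (hex), for lifting and decoding
g_power_table <- function(params, bound) {
  out <- character(bound + 1L)
  out[1] <- "1"
  for (i in seq_len(bound)) {
    out[i + 1L] <- .bn_mulmod(out[i], params$g, params$p)
  }
  out
}

#' Joint key generation for n-of-n decryption
#'
#' Draws one uniform secret share per institution and forms the joint public
#' key \eqn{h = g^{\sum x_i}}. Decryption of any ciphertext requires a
#' partial decryption from every institution; no strict subset of share
#' holders can decrypt. Key generation is simulated centrally and the shares
#' distributed in-process; a distributed ceremony is out of scope.
#'
#' @param params a [pddi_group_params()] object.
#' @param institution_ids character vector of at least 2 distinct ids.
#' @return list with `shares` (named list of `pddi_keyshare`, one per
#'   institution; never serialize these) and `public` (a `pddi_pubkey`
#'   with fields `h`, `n_institutions`, `params`).
#' @examples
#' gp <- pddi_group_params("test")
#' kg <- pddi_keygen(gp, c("screening", "registry"))
#' @export
pddi_keygen <- function(params, institution_ids) {
  stopifnot(inherits(params, "pddi_group"))
  institution_ids <- as.character(institution_ids)
  if (length(institution_ids) < 2 || anyDuplicated(institution_ids))
    stop("joint decryption requires >= 2 distinct institutions")
  shares <- lapply(institution_ids, function(id) {
    structure(list(x = rand_scalar(params), institution_id = id),
              class = "pddi_keyshare")
  })
  names(shares) <- institution_ids
  h <- "1"
  for (s in shares) {
    h <- .bn_mulmod(h, .bn_modexp(params$g, s$x, params$p), params$p)
  }
  public <- structure(
    list(h = h, n_institutions = length(institution_ids), params = params),
    class = "pddi_pubkey")
  list(shares = shares, public = public)
}

#' @export
print.pddi_keyshare <- function(x, ...) {
  cat(sprintf("<key share of institution '%s' (value withheld)>\n",
              x$institution_id))
  invisible(x)
}

#' Encrypt small non-negative integers
#'
#' Probabilistic, additively homomorphic encryption of the message vector
#' `m`: each element becomes \eqn{(g^r, g^m h^r)} with fresh randomness `r`,
#' so repeated encryptions of equal plaintexts are unequal ciphertexts (the
#' property that defeats dictionary attacks on hashed identifiers). The
#' lifted encoding \eqn{g^m} makes ciphertext multiplication add plaintexts.
#'
#' @param pk joint public key from [pddi_keygen()].
#' @param m integer vector, each element in `[0, bound]`.
#' @param bound decodable message bound; defaults to the number of
#'   institutions (the largest possible Bloom-position count).
#' @return A `pddi_ciphertext`: parallel hex vectors `c1`, `c2` plus group
#'   and key fingerprints.
#' @export
pddi_encrypt <- function(pk, m, bound = pk$n_institutions) {
  stopifnot(inherits(pk, "pddi_pubkey"))
  m <- as.integer(m)
  if (any(is.na(m)) || any(m < 0L) || any(m > bound))
    stop(sprintf("plaintexts must lie in [0, %d]", bound))
  params <- pk$params
  n <- length(m)
  r <- rand_scalar(params, n)
  gm <- g_power_table(params, max(bound, 1L))[m + 1L]
  structure(
    list(c1 = .bn_modexp(params$g, r, params$p),
         c2 = .bn_mulmod(gm, .bn_modexp(pk$h, r, params$p), params$p),
         h = pk$h, n_institutions = pk$n_institutions, params = params),
    class = "pddi_ciphertext")
}

#' @export
length.pddi_ciphertext <- function(x) length(x$c1)

#' @export
print.pddi_ciphertext <- function(x, ...) {
  cat(sprintf("<%d ElGamal ciphertext(s), %s-mode group>\n",
              length(x), x$params$mode))
  invisible(x)
}

#' Homomorphic addition of ciphertext vectors
#'
#' Elementwise product of ciphertexts, which decrypts to the elementwise sum
#' of the plaintexts (while the sum stays within the decodable bound).
#'
#' @param a,b `pddi_ciphertext` vectors of equal length under the same group
#'   and public key.
#' @return A `pddi_ciphertext` of the sums.
#' @export
pddi_add <- function(a, b) {
  stopifnot(inherits(a, "pddi_ciphertext"), inherits(b, "pddi_ciphertext"))
  if (!identical(a$params[c("p", "q", "g")], b$params[c("p", "q", "g")]) ||
      !identical(a$h, b$h))
    stop("protocol error: ciphertexts under different groups or keys")
  if (length(a) != length(b))
    stop("protocol error: ciphertext vectors of unequal length")
  structure(
    list(c1 = .bn_mulmod(a$c1, b$c1, a$params$p),
         c2 = .bn_mulmod(a$c2, b$c2, a$params$p),
         h = a$h, n_institutions = a$n_institutions, params = a$params),
    class = "pddi_ciphertext")
}

#' Partial decryption under one institution's share
#'
#' Computes \eqn{d_i = c_1^{x_i}} for every element. Deterministic in its
#' inputs; all n institutions' partials are required to complete decryption.
#'
#' @param ct a `pddi_ciphertext`.
#' @param share a `pddi_keyshare`.
#' @return A `pddi_partial` with hex vector `d` and the institution id.
#' @export
pddi_partial_decrypt <- function(ct, share) {
  stopifnot(inherits(ct, "pddi_ciphertext"), inherits(share, "pddi_keyshare"))
  structure(list(d = .bn_modexp(ct$c1, share$x, ct$params$p),
                 institution_id = share$institution_id),
            class = "pddi_partial")
}

#' Combine partial decryptions and decode
#'
#' Recovers each plaintext as the `m` in `[0, bound]` with
#' \eqn{g^m = c_2 / \prod_i d_i}; the quotient's discrete log is found by
#' lookup against the table of lifted messages, which is exact for the tiny
#' message space used here.
#'
#' @param ct a `pddi_ciphertext` vector.
#' @param partials list of `pddi_partial`, exactly one per institution.
#' @param bound largest decodable plaintext (default: institution count).
#' @param check_complete if `TRUE` (default), refuse to decode unless one
#'   partial per institution is supplied; `FALSE` performs the group
#'   arithmetic regardless, in which case the decoded value is wrong or
#'   undecodable for any strict subset of shares.
#' @return integer vector of plaintexts.
#' @export
pddi_combine_and_decode <- function(ct, partials,
                                    bound = ct$n_institutions,
                                    check_complete = TRUE) {
  stopifnot(inherits(ct, "pddi_ciphertext"))
  ids <- vapply(partials, function(p) p$institution_id, "")
  if (anyDuplicated(ids))
    stop("duplicate partial decryptions from one institution")
  if (check_complete && length(partials) != ct$n_institutions)
    stop(sprintf("decode error: %d partial decryption(s) supplied, %d required",
                 length(partials), ct$n_institutions))
  p <- ct$params$p
  d <- partials[[1]]$d
  for (pp in partials[-1]) d <- .bn_mulmod(d, pp$d, p)
  # invert via Fermat: d^(p-2) mod p
  quot <- .bn_mulmod(ct$c2, .bn_modexp(d, .bn_sub(p, "2"), p), p)
  table <- g_power_table(ct$params, bound)
  m <- match(quot, table) - 1L
  if (anyNA(m))
    stop(sprintf(
      "decode error: %d element(s) outside [0, %d] (corrupted transcript or bound too small)",
      sum(is.na(m)), bound))
  m
}
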