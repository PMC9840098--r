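test_that("joint key equals the product of per-institution components", {
  set.seed(1)
  kg <- fresh_keys(c("A", "B"))
  q <- test_group$q
  p <- test_group$p
  x_sum <- pddi:::`.bn_addmod`(kg$shares$A$x, kg$shares$B$x, q)
  expect_identical(kg$public$h, pddi:::`.bn_modexp`(test_group$g, x_sum, p))

  kg4 <- fresh_keys(c("A", "B", "C", "D"))
  expect_length(unique(vapply(kg4$shares, `[[`, "", "x")), 4L)
  expect_error(pddi_keygen(test_group, "solo"), "2 distinct")
  expect_error(pddi_keygen(test_group, c("A", "A")), "2 distinct")
})

test_that("key generation is reproducible under a fixed seed in test mode", {
  a <- fresh_keys(seed = 123)
  b <- fresh_keys(seed = 123)
  expect_identical(vapply(a$shares, `[[`, "", "x"),
                   vapply(b$shares, `[[`, "", "x"))
  expect_identical(a$public$h, b$public$h)
})

test_that("encrypt/decrypt round trip holds over the message space", {
  set.seed(2)
  for (n_inst in 2:4) {
    kg <- fresh_keys(LETTERS[seq_len(n_inst)])
    m <- sample(0:n_inst, 20, replace = TRUE)
    ct <- pddi_encrypt(kg$public, m)
    expect_identical(decrypt_all(ct, kg), as.integer(m))
  }
  # bounds are enforced
  kg <- fresh_keys()
  expect_error(pddi_encrypt(kg$public, 3L), "\\[0, 2\\]")
  expect_error(pddi_encrypt(kg$public, -1L), "\\[0, 2\\]")
})

test_that("encryption is probabilistic: repeated plaintexts differ", {
  set.seed(3)
  kg <- fresh_keys()
  ct <- pddi_encrypt(kg$public, rep(1L, 1000))
  expect_identical(anyDuplicated(paste(ct$c1, ct$c2)), 0L)
})

test_that("homomorphic addition decrypts to the plaintext sum", {
  set.seed(4)
  kg <- fresh_keys(c("A", "B", "C", "D"))
  expect_identical(decrypt_all(pddi_add(pddi_encrypt(kg$public, 1L),
                                        pddi_encrypt(kg$public, 1L)), kg), 2L)
  for (m in 0:4) {
    s <- pddi_add(pddi_encrypt(kg$public, 0L), pddi_encrypt(kg$public, m))
    expect_identical(decrypt_all(s, kg), as.integer(m))
  }
  bits <- c(1L, 0L, 1L, 1L)
  folded <- Reduce(pddi_add, lapply(bits, function(b)
    pddi_encrypt(kg$public, b, bound = 1L)))
  expect_identical(decrypt_all(folded, kg), sum(bits))
  # vector folding mirrors elementwise integer addition
  a <- pddi_encrypt(kg$public, c(1L, 0L, 1L), bound = 1L)
  b <- pddi_encrypt(kg$public, c(1L, 1L, 0L), bound = 1L)
  expect_identical(decrypt_all(pddi_add(a, b), kg), c(2L, 1L, 1L))
})

test_that("ciphertexts under different keys refuse to combine", {
  set.seed(5)
  kg1 <- fresh_keys()
  kg2 <- fresh_keys()
  expect_error(pddi_add(pddi_encrypt(kg1$public, 1L),
                        pddi_encrypt(kg2$public, 1L)), "protocol error")
})

test_that("partial decryption is deterministic and all shares are required", {
  set.seed(6)
  kg <- fresh_keys(c("A", "B", "C"))
  ct <- pddi_encrypt(kg$public, 2L)
  d1 <- pddi_partial_decrypt(ct, kg$shares$A)
  d2 <- pddi_partial_decrypt(ct, kg$shares$A)
  expect_identical(d1$d, d2$d)

  # a strict subset of shares never reveals the plaintext
  mismatches <- 0L
  for (i in 1:100) {
    m <- sample(0:3, 1)
    ct <- pddi_encrypt(kg$public, m, bound = 3L)
    partials <- lapply(kg$shares[c("A", "B")], function(s)
      pddi_partial_decrypt(ct, s))
    got <- tryCatch(
      pddi_combine_and_decode(ct, partials, bound = 3L,
                              check_complete = FALSE),
      error = function(e) NA_integer_)
    if (is.na(got) || got != m) mismatches <- mismatches + 1L
  }
  expect_gte(mismatches, 99L)
  # and the complete-set check refuses short partial lists outright
  ct <- pddi_encrypt(kg$public, 2L)
  expect_error(
    pddi_combine_and_decode(ct, list(pddi_partial_decrypt(ct, kg$shares$A))),
    "decode error")
})

test_that("decoding detects out-of-range plaintexts", {
  set.seed(7)
  kg <- fresh_keys(c("A", "B", "C", "D"))
  ct <- pddi_encrypt(kg$public, 3L)
  partials <- lapply(kg$shares, function(s) pddi_partial_decrypt(ct, s))
  expect_error(pddi_combine_and_decode(ct, partials, bound = 1L),
               "decode error")
  expect_identical(pddi_combine_and_decode(ct, partials, bound = 4L), 3L)
})

test_that("elementwise encryption is independent of chunking", {
  set.seed(8)
  kg <- fresh_keys()
  m <- sample(0:1, 40, replace = TRUE)
  whole <- pddi_encrypt(kg$public, m, bound = 1L)
  chunked <- pddi_encrypt(kg$public, m[1:13], bound = 1L)
  chunked2 <- pddi_encrypt(kg$public, m[14:40], bound = 1L)
  got <- c(decrypt_all(chunked, kg, bound = 1L),
           decrypt_all(chunked2, kg, bound = 1L))
  expect_identical(got, decrypt_all(whole, kg, bound = 1L))
  expect_identical(got, as.integer(m))
})

test_that("production-mode group satisfies its invariants and round-trips", {
  gp <- pddi_group_params("production")
  expect_gte(pddi:::`.bn_nbits`(gp$q), 224L)
  expect_identical(pddi:::`.bn_modexp`(gp$g, gp$q, gp$p), "1")
  kg <- pddi_keygen(gp, c("A", "B"))
  ct <- pddi_encrypt(kg$public, c(0L, 2L))
  partials <- lapply(kg$shares, function(s) pddi_partial_decrypt(ct, s))
  expect_identical(pddi_combine_and_decode(ct, partials), c(0L, 2L))
})
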