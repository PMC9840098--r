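# Orchestration of the four-step linkage session between the data-holding
# institutions, the semi-honest computation server, and the client. All
# roles run in-process; every message that would cross the network is
# materialized in the transcript with its byte length, and no message body
# ever contains a plaintext identifier or a bare key digest.

new_message <- function(sender, receiver, step, body) {
  list(sender = sender, receiver = receiver, step = step,
       body = body, bytes = nchar(body, type = "bytes"))
}

encode_body <- function(x) {
  jsonlite::base64_enc(charToRaw(
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
}

decode_body <- function(body) {
  jsonlite::fromJSON(rawToChar(jsonlite::base64_dec(body)),
                     simplifyVector = TRUE)
}

# hybrid encryption of an arbitrary string to the client's ElGamal public
# key: KEM c1 = g^r, shared secret SHA-256(h^r), SHA-256 counter keystream
kem_encrypt <- function(plaintext, client_pub, params) {
  r <- rand_scalar(params)
  c1 <- .bn_modexp(params$g, r, params$p)
  shared <- .sha256_hex(paste0("kem:", .bn_modexp(client_pub, r, params$p)))
  data <- charToRaw(enc2utf8(plaintext))
  list(c1 = c1, ct = xor_keystream(data, shared))
}

kem_decrypt <- function(blob, client_share, params) {
  shared <- .sha256_hex(paste0(
    "kem:", .bn_modexp(blob$c1, client_share, params$p)))
  out <- xor_keystream(hex_to_raw(blob$ct), shared, raw_out = TRUE)
  rawToChar(out)
}

xor_keystream <- function(data, key_hex, raw_out = FALSE) {
  n <- length(data)
  blocks <- ceiling(n / 32)
  ks <- unlist(lapply(seq_len(blocks), function(i)
    hex_to_raw(.sha256_hex(paste0(key_hex, ":", i)))))[seq_len(n)]
  out <- as.raw(bitwXor(as.integer(data), as.integer(ks)))
  if (raw_out) out else paste(sprintf("%02x", as.integer(out)), collapse = "")
}

hex_to_raw <- function(h) {
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
}

payload_columns <- function(dataset) {
  setdiff(names(dataset), c("person_uid", unname(ATTRIBUTE_COLUMNS)))
}

#' Run a full privacy-preserving linkage session
#'
#' Executes the four protocol steps end to end over named institution
#' datasets:
#' \enumerate{
#'   \item each institution hashes its matching keys for `combo`, builds a
#'     Bloom filter, encrypts it element-by-element and sends the ciphertext
#'     vector to the server;
#'   \item the server (which holds no decryption key) sums the encrypted
#'     filters homomorphically and returns the encrypted sums;
#'   \item the institutions exchange partial decryptions, decode the summed
#'     filter, extract their own keys present at every institution, and send
#'     the payload rows of those keys to the server encrypted to the client
#'     and tagged with an anonymous link id (a keyed digest under a secret
#'     the server and client never see the inputs of);
#'   \item the server groups the payload rows by link id and forwards the
#'     integrated result to the client, which decrypts the rows. The client
#'     never receives key digests or identifier attributes.
#' }
#'
#' @param datasets named list (>= 2) of person data frames, one per
#'   institution.
#' @param combo matching-key attribute combination (see [make_key()]).
#' @param params group parameters; test mode by default so that large
#'   filter vectors stay fast.
#' @param bloom optional [bloom_params()]; sized automatically for the
#'   largest key set via [bloom_dimension()] when `NULL`.
#' @param client name of the institution acting as client (receives the
#'   integrated payloads); defaults to the first institution, mirroring a
#'   data-holding institution doubling as client.
#' @param seed optional seed (test-mode RNG) for reproducible transcripts.
#' @return A `pddi_session` with elements `result` (a `pddi_result` data
#'   frame: `link_id`, `source`, payload columns), `transcript`
#'   (a `pddi_transcript`), and `n_groups`.
#' @export
run_session <- function(datasets, combo,
                        params = pddi_group_params("test"),
                        bloom = NULL, client = names(datasets)[1],
                        seed = NULL) {
  if (is.null(names(datasets)) || any(names(datasets) == "") ||
      length(datasets) < 2)
    stop("datasets must be a named list of >= 2 institutions")
  if (!client %in% names(datasets))
    stop("client must be one of the institutions")
  combo <- validate_combination(combo)
  ids <- names(datasets)
  n_inst <- length(ids)

  local_seed(seed, {
    keysets <- lapply(datasets, make_key, combo = combo)
    uniq <- lapply(keysets, unique)
    if (is.null(bloom))
      bloom <- bloom_dimension(max(vapply(uniq, length, 0L)))

    kg <- pddi_keygen(params, ids)
    client_x <- rand_scalar(params)
    client_pub <- .bn_modexp(params$g, client_x, params$p)
    link_secret <- rng_hex(16)   # shared by institutions only

    transcript <- list()
    # Step 1: encrypted Bloom filters to the server
    enc_filters <- list()
    for (id in ids) {
      filt <- build_filter(uniq[[id]], bloom)
      ct <- pddi_encrypt(kg$public, filt$bits, bound = 1L)
      enc_filters[[id]] <- ct
      transcript[[length(transcript) + 1L]] <- new_message(
        id, "server", "enc_filter", encode_body(list(c1 = ct$c1, c2 = ct$c2)))
    }

    # Step 2: homomorphic elementwise sum, no decryption at the server
    summed <- Reduce(pddi_add, enc_filters)
    for (id in ids) {
      transcript[[length(transcript) + 1L]] <- new_message(
        "server", id, "summed_filter",
        encode_body(list(c1 = summed$c1, c2 = summed$c2)))
    }

    # partial decryptions exchanged among institutions
    partials <- lapply(ids, function(id)
      pddi_partial_decrypt(summed, kg$shares[[id]]))
    names(partials) <- ids
    for (id in ids) {
      transcript[[length(transcript) + 1L]] <- new_message(
        id, "institutions", "partial_dec",
        encode_body(list(d = partials[[id]]$d)))
    }

    # Step 3: decode counts, extract intersection, encrypt payload rows
    counts <- pddi_combine_and_decode(summed, partials, bound = n_inst)
    payload_msgs <- list()
    for (id in ids) {
      inter <- intersect_mask(counts, uniq[[id]], bloom, n_inst)
      rows <- which(keysets[[id]] %in% inter)
      link <- .sha256_hex(paste0(link_secret, ":", keysets[[id]][rows]))
      cols <- payload_columns(datasets[[id]])
      payload <- datasets[[id]][rows, cols, drop = FALSE]
      body <- lapply(seq_along(rows), function(j) {
        blob <- kem_encrypt(
          jsonlite::toJSON(as.list(payload[j, , drop = FALSE]),
                           auto_unbox = TRUE),
          client_pub, params)
        list(link_id = link[j], c1 = blob$c1, ct = blob$ct)
      })
      payload_msgs[[id]] <- body
      transcript[[length(transcript) + 1L]] <- new_message(
        id, "server", "enc_payload", encode_body(body))
    }

    # Step 4: the server groups by anonymous link id and forwards to the
    # client, which decrypts; key material never reaches the client
    integrated <- list()
    for (id in ids) {
      for (entry in payload_msgs[[id]]) {
        integrated[[length(integrated) + 1L]] <-
          list(link_id = entry$link_id, source = id,
               c1 = entry$c1, ct = entry$ct)
      }
    }
    transcript[[length(transcript) + 1L]] <- new_message(
      "server", client, "integrated", encode_body(integrated))

    rows <- lapply(integrated, function(entry) {
      fields <- jsonlite::fromJSON(
        kem_decrypt(entry[c("c1", "ct")], client_x, params))
      c(list(link_id = entry$link_id, source = entry$source), fields)
    })
    result <- if (length(rows) == 0) {
      data.frame(link_id = character(0), source = character(0))
    } else {
      all_names <- unique(unlist(lapply(rows, names)))
      do.call(rbind, lapply(rows, function(r) {
        missing <- setdiff(all_names, names(r))
        for (mss in missing) r[[mss]] <- NA
        as.data.frame(r[all_names], stringsAsFactors = FALSE)
      }))
    }
    result <- result[order(result$link_id, result$source), , drop = FALSE]
    rownames(result) <- NULL
    class(result) <- c("pddi_result", "data.frame")

    transcript <- structure(transcript, class = "pddi_transcript")
    structure(list(result = result, transcript = transcript,
                   n_groups = length(unique(result$link_id)),
                   combo = combo, bloom = bloom,
                   institutions = ids, client = client),
              class = "pddi_session")
  })
}

#' @export
print.pddi_session <- function(x, ...) {
  cat(sprintf(
    "PDDI session: %d institutions, combo {%s}, %d intersection group(s)\n",
    length(x$institutions), paste(x$combo, collapse = ", "), x$n_groups))
  cat(sprintf("  transcript: %d messages, %d bytes total\n",
              length(x$transcript), transcript_bytes(x$transcript)))
  invisible(x)
}

#' Transcript inspection
#'
#' @param transcript a `pddi_transcript` from [run_session()].
#' @return `transcript_summary`: data frame of (sender, receiver, step,
#'   bytes); `transcript_bytes`: total byte count.
#' @export
transcript_summary <- function(transcript) {
  data.frame(sender = vapply(transcript, `[[`, "", "sender"),
             receiver = vapply(transcript, `[[`, "", "receiver"),
             step = vapply(transcript, `[[`, "", "step"),
             bytes = vapply(transcript, `[[`, 0, "bytes"),
             stringsAsFactors = FALSE)
}

#' @rdname transcript_summary
#' @export
transcript_bytes <- function(transcript) {
  sum(vapply(transcript, `[[`, 0, "bytes"))
}

#' @export
print.pddi_transcript <- function(x, ...) {
  print(transcript_summary(x))
  invisible(x)
}

#' Write / read a protocol transcript as JSON lines
#'
#' One message per line with fields sender, receiver, step, body (base64)
#' and bytes.
#'
#' @param transcript a `pddi_transcript`.
#' @param path file path.
#' @export
write_transcript <- function(transcript, path) {
  lines <- vapply(transcript, function(m)
    jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  msgs <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  structure(msgs, class = "pddi_transcript")
}

#' Matched pairs from a session result
#'
#' Joins the integrated payload groups back to row numbers of two
#' institutions' datasets via their serial-id payload column, yielding the
#' (row_a, row_b) pairs the linkage produced. This is evaluation-side
#' plumbing: it uses only payload fields the client legitimately holds.
#'
#' @param session a `pddi_session`.
#' @param datasets the named dataset list given to [run_session()].
#' @param id_cols named character vector mapping institution name to its
#'   serial-id payload column.
#' @return data frame with one row per cross-institution pair:
#'   `row_<institution>` columns of row indices.
#' @export
session_pairs <- function(session, datasets,
                          id_cols = c(screening = "screening_id",
                                      registry = "registry_id")) {
  res <- session$result
  ids <- session$institutions
  stopifnot(all(ids %in% names(id_cols)))
  per_source <- lapply(ids, function(id) {
    sub <- res[res$source == id, , drop = FALSE]
    data.frame(link_id = sub$link_id,
               row = match(sub[[id_cols[[id]]]], datasets[[id]][[id_cols[[id]]]]))
  })
  names(per_source) <- ids
  out <- per_source[[1]]
  names(out)[2] <- paste0("row_", ids[1])
  for (id in ids[-1]) {
    nxt <- per_source[[id]]
    names(nxt)[2] <- paste0("row_", id)
    out <- merge(out, nxt, by = "link_id")
  }
  out
}
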