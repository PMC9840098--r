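# Scoring a linkage run against ground truth: confusion counts, matching
# sensitivity/specificity, and attribute-combination sweeps. The screening
# dataset is the reference: each screening record is classified by whether
# the linkage matched it and whether the match was the right person.

#' Confusion counts of a linkage run
#'
#' Construct confusion counts directly, or reconstruct the full 2x2 table
#' from reported false positives/negatives plus the design sizes (reports of
#' matching experiments typically print only fp and fn): `tp = n_common -
#' fn`, `tn = n_screening - n_common - fp`.
#'
#' @param fp,fn false positives / false negatives (screening records).
#' @param n_common number of true common persons.
#' @param n_screening screening table size.
#' @return A `pddi_confusion` with fields `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(fp = 3, fn = 27, n_common = 60, n_screening = 2000)
#' @export
confusion_counts <- function(fp, fn, n_common, n_screening) {
  tp <- n_common - fn
  tn <- n_screening - n_common - fp
  if (tp < 0 || tn < 0) stop("inconsistent confusion counts")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "pddi_confusion")
}

#' @export
print.pddi_confusion <- function(x, ...) {
  cat(sprintf("matching confusion: tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Score matched pairs against ground truth
#'
#' Per screening record: matched to its true counterpart -> true positive;
#' not matched to its counterpart though one exists -> false negative;
#' matched to at least one wrong person -> (also) a false positive;
#' non-common and unmatched -> true negative. A record matched to both its
#' counterpart and a stranger contributes one tp and one fp.
#'
#' @param pairs data frame of matched `(screening_row, registry_row)` pairs.
#' @param truth ground-truth link table (`person_uid`, `screening_row`,
#'   `registry_row`).
#' @param n_screening screening table size.
#' @return A `pddi_confusion`.
#' @export
score_matches <- function(pairs, truth, n_screening) {
  n_common <- nrow(truth)
  true_reg <- rep(NA_integer_, n_screening)
  true_reg[truth$screening_row] <- truth$registry_row
  correct <- pairs$registry_row == true_reg[pairs$screening_row]
  correct[is.na(correct)] <- FALSE
  tp <- length(unique(pairs$screening_row[correct]))
  wrong_rows <- unique(pairs$screening_row[!correct])
  fp <- length(wrong_rows)
  matched_rows <- unique(pairs$screening_row)
  noncommon <- setdiff(seq_len(n_screening), truth$screening_row)
  tn <- length(setdiff(noncommon, matched_rows))
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(n_common - tp), tn = as.integer(tn)),
            class = "pddi_confusion")
}

# pair-free scoring from key vectors: per screening record, does the
# registry hold its true counterpart's key (tp) and how many other rows
# share its key (fp). Equivalent to score_matches() over the all-pairs
# join, but O(n) even for weak combinations that match almost everything.
score_keys <- function(ks, kr, truth, n_screening) {
  uk <- unique(kr)
  cnt <- tabulate(match(kr, uk), nbins = length(uk))
  cr <- cnt[match(ks, uk)]
  cr[is.na(cr)] <- 0L
  true_reg <- rep(NA_integer_, n_screening)
  true_reg[truth$screening_row] <- truth$registry_row
  correct <- !is.na(true_reg) & kr[ifelse(is.na(true_reg), 1L, true_reg)] == ks
  wrong <- cr - as.integer(correct)
  structure(list(tp = sum(correct), fp = sum(wrong > 0),
                 fn = nrow(truth) - sum(correct),
                 tn = sum(cr == 0 & is.na(true_reg))),
            class = "pddi_confusion")
}

#' Matching sensitivity and specificity
#'
#' `sensitivity = 100 tp / (tp + fn)`, `specificity = 100 tn / (tn + fp)`,
#' as percentages printed to 2 decimals with half-up rounding. The
#' specificity denominator is the screening-side records without a true
#' counterpart.
#'
#' @param counts a `pddi_confusion`.
#' @return A `pddi_matching_accuracy` with raw and 2-decimal percent values.
#' @examples
#' accuracy(confusion_counts(3, 27, 60, 2000))   # 55.00 / 99.85
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "pddi_confusion"))
  if (counts$tp + counts$fn == 0 || counts$tn + counts$fp == 0)
    stop("undefined matching accuracy: zero denominator")
  se <- 100 * counts$tp / (counts$tp + counts$fn)
  sp <- 100 * counts$tn / (counts$tn + counts$fp)
  structure(list(sensitivity = round_half_up(se, 2),
                 specificity = round_half_up(sp, 2),
                 sensitivity_raw = se, specificity_raw = sp,
                 counts = counts),
            class = "pddi_matching_accuracy")
}

#' @export
print.pddi_matching_accuracy <- function(x, ...) {
  cat(sprintf("matching sensitivity %.2f%%, specificity %.2f%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Plaintext exact-match linkage (fast path)
#'
#' Joins two tables on equal compressed keys for a combination, bypassing
#' the cryptographic protocol; used for combination sweeps and as the
#' reference the protocol path must agree with.
#'
#' @param screening,registry person data frames.
#' @param combo attribute combination.
#' @return data frame of matched `(screening_row, registry_row)` pairs.
#' @export
match_plaintext <- function(screening, registry, combo) {
  match_keys(make_key(screening, combo), make_key(registry, combo))
}

match_keys <- function(ks, kr) {
  shared <- intersect(ks, kr)   # keys absent from one side can never pair
  si <- which(ks %in% shared)
  ri <- which(kr %in% shared)
  sk <- data.frame(key = ks[si], screening_row = si,
                   stringsAsFactors = FALSE)
  rk <- data.frame(key = kr[ri], registry_row = ri,
                   stringsAsFactors = FALSE)
  out <- merge(sk, rk, by = "key")
  out <- out[order(out$screening_row, out$registry_row),
             c("screening_row", "registry_row")]
  rownames(out) <- NULL
  out
}

#' Sweep matching accuracy over attribute combinations
#'
#' Links the pair once per combination and scores each run, reproducing the
#' shape of a matching-experiment report: one row per combination with its
#' false positives, false negatives, sensitivity and specificity. The
#' `protocol` mode runs the full encrypted session per combination and must
#' give counts identical to the plaintext path.
#'
#' @param pair a `pddi_pair` from [build_linked_pair()].
#' @param combos list of combinations; defaults to all subsets of the six
#'   default attributes (26 subsets of the five non-sex attributes when the
#'   pair's population is single-sex).
#' @param mode `"plaintext"` or `"protocol"`.
#' @param params group parameters for protocol mode.
#' @param seed seed for protocol mode sessions.
#' @return data frame: combination, fp, fn, tp, tn, sensitivity, specificity.
#' @export
sweep_combinations <- function(pair, combos = NULL,
                               mode = c("plaintext", "protocol"),
                               params = pddi_group_params("test"),
                               seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(pair, "pddi_pair"))
  if (is.null(combos)) {
    attrs <- DEFAULT_KEY_ATTRIBUTES
    if (length(unique(pair$screening$sex)) == 1)
      attrs <- setdiff(attrs, "sex")
    combos <- enumerate_combinations(attrs)
  }
  attrs_used <- sort(unique(unlist(combos)))
  cf_s <- canonical_frame(pair$screening, attrs_used)
  cf_r <- canonical_frame(pair$registry, attrs_used)
  rows <- lapply(combos, function(combo) {
    counts <- if (mode == "plaintext") {
      score_keys(key_from_canonical(cf_s, combo),
                 key_from_canonical(cf_r, combo),
                 pair$truth, nrow(pair$screening))
    } else {
      sess <- run_session(list(screening = pair$screening,
                               registry = pair$registry),
                          combo, params = params, seed = seed)
      sp <- session_pairs(sess, list(screening = pair$screening,
                                     registry = pair$registry))
      score_matches(data.frame(screening_row = sp$row_screening,
                               registry_row = sp$row_registry),
                    pair$truth, nrow(pair$screening))
    }
    acc <- accuracy(counts)
    data.frame(combination = paste(combo, collapse = "+"),
               fp = counts$fp, fn = counts$fn, tp = counts$tp, tn = counts$tn,
               sensitivity = acc$sensitivity, specificity = acc$specificity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
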