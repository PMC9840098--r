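# Canonicalization of identifier attributes and construction of compressed
# (hashed) matching keys for arbitrary attribute combinations.

#' Matching-key attributes
#'
#' The seven identifier attributes a person record may carry. Japanese names
#' are recorded in two scripts, so each name field contributes two separate
#' attributes (kanji and kana). `KEY_ATTRIBUTES` lists all seven;
#' `DEFAULT_KEY_ATTRIBUTES` is the six-attribute set used for matching by
#' default (address is available but excluded, reflecting its poor stability
#' as an exact-match key).
#'
#' @format Character vectors.
#' @export
KEY_ATTRIBUTES <- c("family_kanji", "family_kana", "first_kanji",
                    "first_kana", "birth_date", "sex", "address")

#' @rdname KEY_ATTRIBUTES
#' @export
DEFAULT_KEY_ATTRIBUTES <- KEY_ATTRIBUTES[1:6]

# attribute name -> column name in the CSV schema
ATTRIBUTE_COLUMNS <- c(
  family_kanji = "family_name_kanji", family_kana = "family_name_kana",
  first_kanji = "first_name_kanji", first_kana = "first_name_kana",
  birth_date = "birth_date", sex = "sex", address = "address")

attribute_column <- function(records, attr) {
  if (attr %in% names(records)) return(records[[attr]])
  col <- ATTRIBUTE_COLUMNS[[attr]]
  if (!col %in% names(records))
    stop(sprintf("records lack attribute column '%s'", col))
  records[[col]]
}

#' Canonicalize one identifier attribute
#'
#' Exact-match linkage is only meaningful after both institutions map their
#' raw values onto a shared canonical form: Unicode NFKC normalization (which
#' folds full-width digits and half-width kana to their compatibility forms),
#' whitespace stripping, ISO-8601 birth dates, and `M`/`F`/`U` sex codes.
#' Missing values canonicalize to the empty string, so two records missing
#' the same field still agree on it.
#'
#' @param x character vector of raw values.
#' @param attr one of [KEY_ATTRIBUTES].
#' @return character vector of canonical values.
#' @examples
#' canonicalize_attribute("１９９７-09-11", "birth_date")
#' canonicalize_attribute("  Tanaka ", "family_kana")
#' @export
canonicalize_attribute <- function(x, attr) {
  attr <- match.arg(attr, KEY_ATTRIBUTES)
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- stringi::stri_trim_both(stringi::stri_trans_nfkc(x))
  if (attr == "birth_date") {
    out <- canonicalize_date(out)
  } else if (attr == "sex") {
    out <- canonicalize_sex(out)
  }
  out
}

canonicalize_date <- function(x) {
  out <- character(length(x))
  idx <- which(x != "")
  if (length(idx) == 0) return(out)
  v <- gsub("[/.年月]", "-", x[idx])  # separators incl. 年/月
  v <- gsub("日", "", v)                  # trailing 日
  eight <- grepl("^[0-9]{8}$", v)
  v[eight] <- paste(substr(v[eight], 1, 4), substr(v[eight], 5, 6),
                    substr(v[eight], 7, 8), sep = "-")
  m <- regmatches(v, regexec("^([0-9]{4})-([0-9]{1,2})-([0-9]{1,2})$", v))
  ok <- lengths(m) == 4
  if (!all(ok))
    stop(sprintf("cannot canonicalize birth date '%s'", x[idx][!ok][1]))
  iso <- sprintf("%s-%02d-%02d",
                 vapply(m, `[`, "", 2),
                 as.integer(vapply(m, `[`, "", 3)),
                 as.integer(vapply(m, `[`, "", 4)))
  d <- as.Date(iso, format = "%Y-%m-%d")
  bad <- is.na(d) | format(d, "%Y-%m-%d") != iso
  if (any(bad))
    stop(sprintf("cannot canonicalize birth date '%s'", x[idx][bad][1]))
  out[idx] <- iso
  out
}

canonicalize_sex <- function(x) {
  lut <- c(m = "M", male = "M", "男" = "M", "1" = "M",
           f = "F", female = "F", "女" = "F", "2" = "F")
  key <- tolower(x)
  out <- unname(lut[key])
  out[x == ""] <- ""
  out[is.na(out) & x != ""] <- "U"
  out
}

#' Compressed matching keys
#'
#' Builds the irreversible compressed key of each record for a given
#' attribute combination: the SHA-256 digest of the canonical attribute
#' values joined in fixed attribute order with the U+001F unit separator.
#' Two records obtain equal keys exactly when they agree on every attribute
#' of the combination after canonicalization.
#'
#' @param records data frame of person records (canonical attribute names or
#'   the CSV column names are both accepted).
#' @param combo character vector of >= 2 attributes from [KEY_ATTRIBUTES].
#' @return character vector of 64-character hex digests, one per row.
#' @export
make_key <- function(records, combo) {
  combo <- validate_combination(combo)
  key_from_canonical(canonical_frame(records, combo), combo)
}

# canonicalize a set of attributes once; reusable across combinations
canonical_frame <- function(records, attrs = KEY_ATTRIBUTES) {
  out <- lapply(attrs, function(a)
    canonicalize_attribute(attribute_column(records, a), a))
  names(out) <- attrs
  out
}

key_from_canonical <- function(cf, combo) {
  combo <- validate_combination(combo)
  joined <- do.call(paste, c(cf[combo], sep = "\x1f"))
  .sha256_hex(joined)
}

validate_combination <- function(combo) {
  combo <- as.character(combo)
  bad <- setdiff(combo, KEY_ATTRIBUTES)
  if (length(bad))
    stop(sprintf("unknown matching attribute(s): %s",
                 paste(bad, collapse = ", ")))
  if (length(combo) < 2 || anyDuplicated(combo))
    stop("a matching-key combination needs >= 2 distinct attributes")
  # fixed canonical order, independent of how the caller listed them
  KEY_ATTRIBUTES[sort(match(combo, KEY_ATTRIBUTES))]
}

#' Enumerate attribute combinations
#'
#' All subsets of `attrs` of size at least `min_size`, ordered by size and
#' then lexicographically. With the default six attributes this yields the
#' 57 combinations \eqn{\sum_{k=2}^{6} \binom{6}{k}}; dropping sex (as when
#' every screening subject is female) leaves 26.
#'
#' @param attrs attribute set, by default [DEFAULT_KEY_ATTRIBUTES].
#' @param min_size smallest subset size, at least 2 (single-attribute
#'   matching is excluded: it floods the linkage with false positives).
#' @return list of character vectors.
#' @examples
#' length(enumerate_combinations())                             # 57
#' length(enumerate_combinations(setdiff(DEFAULT_KEY_ATTRIBUTES, "sex")))  # 26
#' @export
enumerate_combinations <- function(attrs = DEFAULT_KEY_ATTRIBUTES,
                                   min_size = 2) {
  attrs <- unique(as.character(attrs))
  if (length(attrs) == 0) stop("empty attribute set")
  if (min_size < 2) stop("min_size must be >= 2")
  attrs <- sort(attrs)
  out <- list()
  if (min_size > length(attrs)) return(out)
  for (k in seq(min_size, length(attrs))) {
    sets <- utils::combn(attrs, k, simplify = FALSE)
    ord <- order(vapply(sets, paste, "", collapse = "\x1f"))
    out <- c(out, sets[ord])
  }
  out
}
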