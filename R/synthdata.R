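# Synthetic linked screening/registry dataset pairs with a planted common
# subset and identifier errors injected at exact per-category counts.

KANA_POOL <- strsplit(paste0(
  "アイウエオカキクケコサシスセソタチツテトナニヌネノ",
  "ハヒフヘホマミムメモヤユヨラリルレロワ"), "")[[1]]
KANJI_POOL <- strsplit("田中山川本村木林森石井原野松竹梅", "")[[1]]

lexicon_env <- new.env(parent = emptyenv())

#' Load the built-in name/address lexicons and substitution tables
#'
#' Small editable TSV tables under `inst/extdata/`: internally consistent
#' kanji/kana surname and given-name pairs, place-name components, and the
#' homophone-kanji and variant-kanji substitution tables used by the error
#' operators. All entries are synthetic and illustrative; the tables are
#' pluggable so other scripts or languages can be simulated by pointing
#' `dir` elsewhere.
#'
#' @param dir directory holding the TSV files; defaults to the installed
#'   package copies.
#' @return list of data frames `family`, `first`, `places`, `homophones`,
#'   `variants`.
#' @export
load_lexicons <- function(dir = system.file("extdata", package = "pddi")) {
  cached <- lexicon_env$cache
  if (!is.null(cached) && identical(lexicon_env$dir, dir)) return(cached)
  tsv <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop(sprintf("lexicon file missing: %s", path))
    df <- read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
    if (nrow(df) == 0) stop(sprintf("empty lexicon: %s", name))
    df
  }
  lex <- list(family = tsv("family_names.tsv"),
              first = tsv("first_names.tsv"),
              places = tsv("placenames.tsv"),
              homophones = tsv("homophone_kanji.tsv"),
              variants = tsv("variant_kanji.tsv"))
  lexicon_env$cache <- lex
  lexicon_env$dir <- dir
  lex
}

#' Generate a synthetic person population
#'
#' Draws `n` person records with internally consistent kanji/kana name
#' pairs, uniform birth dates over 1935--2004, plausible Japanese addresses
#' (place-name components plus block numbers), and a stable ground-truth
#' `person_uid` that no error operator ever perturbs.
#'
#' @param n number of records (> 0).
#' @param seed optional RNG seed; the same seed reproduces the same
#'   population byte for byte. `NULL` uses the ambient RNG stream.
#' @param sex force all records to `"M"` or `"F"` (e.g. a breast-cancer
#'   screening population); `NULL` mixes sexes via the given-name lexicon.
#' @param lexicons see [load_lexicons()].
#' @param uid_prefix prefix for the ground-truth person uid.
#' @return data frame with the CSV identifier columns.
#' @export
generate_population <- function(n, seed = NULL, sex = NULL,
                                lexicons = load_lexicons(),
                                uid_prefix = "P") {
  n <- as.integer(n)
  if (is.na(n) || n <= 0) stop("population size must be positive")
  local_seed(seed, {
    fam <- lexicons$family[sample.int(nrow(lexicons$family), n, TRUE), ]
    pool <- lexicons$first
    if (!is.null(sex)) {
      pool <- pool[pool$sex == sex, , drop = FALSE]
      if (nrow(pool) == 0) stop("no given names for requested sex")
    }
    fst <- pool[sample.int(nrow(pool), n, TRUE), ]
    days <- sample.int(as.integer(as.Date("2004-12-31") -
                                  as.Date("1935-01-01")) + 1L, n, TRUE) - 1L
    birth <- format(as.Date("1935-01-01") + days, "%Y-%m-%d")
    pl <- lexicons$places[sample.int(nrow(lexicons$places), n, TRUE), ]
    address <- paste0(pl$prefecture, pl$city, pl$town,
                      sample.int(30L, n, TRUE), "-",
                      sample.int(20L, n, TRUE), "-",
                      sample.int(15L, n, TRUE))
    data.frame(
      person_uid = sprintf("%s%07d", uid_prefix, seq_len(n)),
      family_name_kanji = fam$kanji, family_name_kana = fam$kana,
      first_name_kanji = fst$kanji, first_name_kana = fst$kana,
      sex = fst$sex, birth_date = birth, address = address,
      stringsAsFactors = FALSE)
  })
}

## ---- error operators ------------------------------------------------------

ERROR_CATEGORIES <- list(
  typing = c("name", "birth_date", "address", "sex"),
  kanji_conversion = c("name", "address"),
  misreading = "name",
  missing_letter = "name",
  omission = c("name", "address"),
  variant_kanji = "name",
  address_format = "address",
  name_change = "name",
  alias = "name",
  moving = "address")

# categories whose single error event changes both scripts of a name,
# leaving the record unmatched on >= 2 canonical key attributes
spans_both_scripts <- function(category, class) {
  class == "name" &&
    category %in% c("typing", "omission", "name_change", "alias")
}

substitute_char <- function(s, pool) {
  if (nchar(s) == 0) return(sample(pool, 1))
  chars <- strsplit(s, "")[[1]]
  pos <- sample.int(length(chars), 1)
  choices <- setdiff(pool, chars[pos])
  if (length(choices) == 0) choices <- pool
  chars[pos] <- sample(choices, 1)
  paste(chars, collapse = "")
}

delete_char <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (length(chars) < 2) return("")
  paste(chars[-sample.int(length(chars), 1)], collapse = "")
}

table_swap <- function(s, tab, fallback_pool) {
  chars <- strsplit(s, "")[[1]]
  hits <- which(chars %in% tab[[1]])
  if (length(hits) > 0) {
    pos <- hits[sample.int(length(hits), 1)]
    alts <- strsplit(tab[[2]][match(chars[pos], tab[[1]])], ",")[[1]]
    chars[pos] <- sample(alts, 1)
    return(paste(chars, collapse = ""))
  }
  substitute_char(s, fallback_pool)
}

name_cols <- function(side) {
  c(kanji = paste0(side, "_name_kanji"), kana = paste0(side, "_name_kana"))
}

# applies one error instance in place; returns list(row, attrs) where attrs
# are the canonical key attributes the instance is meant to break
apply_error_instance <- function(row, category, class, side, lexicons) {
  attr_of <- function(side, script) paste0(side, "_", script)
  cols <- if (class == "name") name_cols(side) else NULL
  attrs <- character(0)
  if (category == "typing" && class == "name") {
    row[[cols["kana"]]] <- substitute_char(row[[cols["kana"]]], KANA_POOL)
    row[[cols["kanji"]]] <- substitute_char(row[[cols["kanji"]]], KANJI_POOL)
    attrs <- attr_of(side, c("kanji", "kana"))
  } else if (category == "typing" && class == "birth_date") {
    d <- row$birth_date
    if (runif(1) < 0.5) {
      day <- as.integer(substr(d, 9, 10))
      new_day <- sample(setdiff(1:28, day), 1)
      row$birth_date <- sprintf("%s-%02d", substr(d, 1, 7), new_day)
    } else {
      y4 <- as.integer(substr(d, 4, 4))
      row$birth_date <- paste0(substr(d, 1, 3),
                               sample(setdiff(0:9, y4), 1), substr(d, 5, 10))
    }
    attrs <- "birth_date"
  } else if (category == "typing" && class == "sex") {
    row$sex <- if (identical(row$sex, "F")) "M" else "F"
    attrs <- "sex"
  } else if (category == "typing" && class == "address") {
    a <- row$address
    if (grepl("[0-9]", a)) {
      chars <- strsplit(a, "")[[1]]
      digs <- which(chars %in% as.character(0:9))
      pos <- digs[sample.int(length(digs), 1)]
      chars[pos] <- sample(setdiff(as.character(0:9), chars[pos]), 1)
      row$address <- paste(chars, collapse = "")
    } else {
      row$address <- substitute_char(a, KANA_POOL)
    }
    attrs <- "address"
  } else if (category == "kanji_conversion" && class == "name") {
    row[[cols["kanji"]]] <- table_swap(row[[cols["kanji"]]],
                                       lexicons$homophones, KANJI_POOL)
    attrs <- attr_of(side, "kanji")
  } else if (category == "kanji_conversion" && class == "address") {
    row$address <- table_swap(row$address, lexicons$homophones, KANJI_POOL)
    attrs <- "address"
  } else if (category == "misreading") {
    row[[cols["kana"]]] <- substitute_char(row[[cols["kana"]]], KANA_POOL)
    attrs <- attr_of(side, "kana")
  } else if (category == "missing_letter") {
    row[[cols["kana"]]] <- delete_char(row[[cols["kana"]]])
    attrs <- attr_of(side, "kana")
  } else if (category == "omission" && class == "name") {
    row[[cols["kanji"]]] <- ""
    row[[cols["kana"]]] <- ""
    attrs <- attr_of(side, c("kanji", "kana"))
  } else if (category == "omission" && class == "address") {
    stripped <- sub("[0-9-]+$", "", row$address)
    row$address <- if (identical(stripped, row$address))
      substr(row$address, 1, nchar(row$address) - 1) else stripped
    attrs <- "address"
  } else if (category == "variant_kanji") {
    row[[cols["kanji"]]] <- table_swap(row[[cols["kanji"]]],
                                       lexicons$variants, KANJI_POOL)
    attrs <- attr_of(side, "kanji")
  } else if (category == "address_format") {
    a <- row$address
    m <- regexec("^(.*?)([0-9]+)-([0-9]+)-([0-9]+)$", a)[[1]]
    if (m[1] != -1) {
      g <- regmatches(a, regexec("^(.*?)([0-9]+)-([0-9]+)-([0-9]+)$", a))[[1]]
      # reflow block numbers into the 丁目/番/号 style, optionally with
      # full-width digits (NFKC folds the digits back, the style remains)
      digits <- c(g[3], g[4], g[5])
      if (runif(1) < 0.5)
        digits <- vapply(digits, function(d) stringi::stri_trans_general(
          d, "Halfwidth-Fullwidth"), "")
      row$address <- paste0(g[2], digits[1], "丁目", digits[2],
                            "番", digits[3], "号")
    } else {
      row$address <- paste0(a, "番地")
    }
    attrs <- "address"
  } else if (category == "name_change") {
    repeat {
      pick <- lexicons$family[sample.int(nrow(lexicons$family), 1), ]
      if (!identical(pick$kanji, row$family_name_kanji)) break
    }
    row$family_name_kanji <- pick$kanji
    row$family_name_kana <- pick$kana
    attrs <- c("family_kanji", "family_kana")
  } else if (category == "alias") {
    pool <- lexicons$first
    same_sex <- pool[pool$sex == row$sex, , drop = FALSE]
    if (nrow(same_sex) > 1) pool <- same_sex
    repeat {
      pick <- pool[sample.int(nrow(pool), 1), ]
      if (!identical(pick$kanji, row$first_name_kanji)) break
    }
    row$first_name_kanji <- pick$kanji
    row$first_name_kana <- pick$kana
    attrs <- c("first_kanji", "first_kana")
  } else if (category == "moving") {
    repeat {
      new_addr <- generate_population(1, lexicons = lexicons)$address
      if (!identical(new_addr, row$address)) break
    }
    row$address <- new_addr
    attrs <- "address"
  } else {
    stop(sprintf("unknown error category/attribute: %s/%s", category, class))
  }
  list(row = row, attrs = attrs)
}

#' Apply one identifier-error operator to a record
#'
#' Perturbs exactly the targeted attribute(s) of one record according to the
#' category semantics (a typo substitutes a character, a kanji-conversion
#' error swaps a homophone while the reading stays intact, a misreading
#' alters the kana while the kanji stays byte-identical, and so on). The
#' ground-truth `person_uid` is never touched.
#'
#' @param record one-row data frame in the person CSV schema.
#' @param category error category name (see `names(ERROR_CATEGORIES)`
#'   internally): `typing`, `kanji_conversion`, `misreading`,
#'   `missing_letter`, `omission`, `variant_kanji`, `address_format`,
#'   `name_change`, `alias`, `moving`.
#' @param attribute attribute class the category targets: `name`,
#'   `birth_date`, `address` or `sex`.
#' @param side for name errors, `"family"` or `"first"`.
#' @param seed optional RNG seed for reproducibility.
#' @param lexicons see [load_lexicons()].
#' @return list with the perturbed `record` and `attrs`, the canonical key
#'   attributes the error breaks.
#' @export
apply_error <- function(record, category, attribute = NULL, side = "family",
                        seed = NULL, lexicons = load_lexicons()) {
  if (!category %in% names(ERROR_CATEGORIES))
    stop(sprintf("unknown error category '%s'", category))
  allowed <- ERROR_CATEGORIES[[category]]
  attribute <- attribute %||% allowed[1]
  if (!attribute %in% allowed)
    stop(sprintf("category '%s' does not target attribute class '%s'",
                 category, attribute))
  stopifnot(nrow(record) == 1)
  local_seed(seed, {
    res <- apply_error_instance(record, category, attribute, side, lexicons)
    res$row$person_uid <- record$person_uid
    list(record = res$row, attrs = res$attrs)
  })
}

## ---- error plans ----------------------------------------------------------

#' Identifier-error plans
#'
#' An error plan fixes, for one dataset pair, how many common records carry
#' each (category, attribute-class) error, how many records end up unmatched
#' on two or more key attributes, and how many records are perturbed at all.
#' The built-in `colorectal` and `breast` plans carry the exact counts of
#' the error taxonomy the package's evaluation experiments use: 51 of 60
#' common records perturbed (25 on multiple keys) for the colorectal pair
#' and 36 of 62 (14 on multiple keys) for the breast pair.
#'
#' @param items data frame with columns `category`, `attribute`
#'   (class: name/birth_date/address/sex) and `count`.
#' @param multi_key number of records that must be unmatched on >= 2
#'   canonical key attributes.
#' @param total number of distinct records perturbed.
#' @return A `pddi_error_plan`.
#' @export
error_plan <- function(items, multi_key, total) {
  items <- items[items$count > 0, , drop = FALSE]
  for (i in seq_len(nrow(items))) {
    cat_i <- items$category[i]
    if (!cat_i %in% names(ERROR_CATEGORIES) ||
        !items$attribute[i] %in% ERROR_CATEGORIES[[cat_i]])
      stop(sprintf("plan error: category '%s' cannot target '%s'",
                   cat_i, items$attribute[i]))
  }
  if (multi_key > total)
    stop("plan error: multi-key record count exceeds total perturbed")
  structure(list(items = items, multi_key = as.integer(multi_key),
                 total = as.integer(total)),
            class = "pddi_error_plan")
}

plan_items <- function(...) {
  rows <- list(...)
  data.frame(category = vapply(rows, `[[`, "", 1),
             attribute = vapply(rows, `[[`, "", 2),
             count = as.integer(vapply(rows, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' @rdname error_plan
#' @export
colorectal_error_plan <- function() {
  error_plan(plan_items(
    c("typing", "name", "3"), c("typing", "birth_date", "15"),
    c("typing", "address", "6"), c("typing", "sex", "5"),
    c("kanji_conversion", "name", "5"), c("kanji_conversion", "address", "2"),
    c("misreading", "name", "10"), c("missing_letter", "name", "2"),
    c("omission", "address", "4"), c("omission", "name", "10"),
    c("variant_kanji", "name", "7"), c("address_format", "address", "5"),
    c("name_change", "name", "2"), c("alias", "name", "2"),
    c("moving", "address", "2")),
    multi_key = 25, total = 51)
}

#' @rdname error_plan
#' @export
breast_error_plan <- function() {
  error_plan(plan_items(
    c("typing", "name", "1"), c("typing", "address", "2"),
    c("kanji_conversion", "name", "6"), c("misreading", "name", "8"),
    c("missing_letter", "name", "1"), c("omission", "name", "1"),
    c("variant_kanji", "name", "4"), c("address_format", "address", "15"),
    c("name_change", "name", "1"), c("moving", "address", "8")),
    multi_key = 14, total = 36)
}

#' @rdname error_plan
#' @export
zero_error_plan <- function() {
  error_plan(plan_items()[0, ], multi_key = 0, total = 0)
}

# Deterministic constructive assignment of plan instances to record slots
# 1..total. Slots 1..multi_key become multi-key records. Returns a list of
# per-slot instance data frames (category, attribute class).
allocate_errors <- function(plan) {
  items <- plan$items
  inst <- items[rep(seq_len(nrow(items)), items$count),
                c("category", "attribute")]
  if (nrow(inst) == 0) {
    if (plan$total != 0) stop("plan error: no instances but total > 0")
    return(list())
  }
  span <- mapply(spans_both_scripts, inst$category, inst$attribute)
  i2 <- inst[span, , drop = FALSE]
  i1 <- inst[!span, , drop = FALSE]
  S <- plan$total - plan$multi_key
  Mt <- plan$multi_key
  if (nrow(i2) > Mt)
    stop("plan error: more multi-attribute instances than multi-key records")
  pairs_needed <- Mt - nrow(i2)
  if (nrow(i1) < S + 2 * pairs_needed)
    stop("plan error: too few single-attribute instances for the marginals")

  # pair single-attribute instances on distinct key classes for the multi
  # records not served by a spanning instance
  key_class <- function(a) if (a == "name") "name" else a
  queues <- split(seq_len(nrow(i1)), vapply(i1$attribute, key_class, ""))
  pairs <- list()
  for (pi in seq_len(pairs_needed)) {
    sizes <- vapply(queues, length, 0L)
    ord <- order(-sizes, names(sizes))
    a <- ord[1]
    b <- if (length(ord) > 1 && sizes[ord[2]] > 0) ord[2] else NA
    if (is.na(b) || sizes[b] == 0) {
      if (names(sizes)[a] == "name" && sizes[a] >= 2) b <- a
      else stop("plan error: cannot pair errors on distinct attributes")
    }
    take <- c(queues[[a]][1], queues[[b]][if (a == b) 2 else 1])
    queues[[a]] <- setdiff(queues[[a]], take)
    queues[[b]] <- setdiff(queues[[b]], take)
    pairs[[pi]] <- take
  }
  used <- unlist(pairs)
  rest <- setdiff(seq_len(nrow(i1)), used)
  singles_idx <- rest[seq_len(S)]
  leftover <- setdiff(rest, singles_idx)

  slots <- vector("list", plan$total)
  # multi slots: spanning instances first, then the distinct-class pairs
  for (i in seq_len(nrow(i2))) slots[[i]] <- i2[i, , drop = FALSE]
  for (pi in seq_along(pairs))
    slots[[nrow(i2) + pi]] <- i1[pairs[[pi]], , drop = FALSE]
  for (si in seq_along(singles_idx))
    slots[[Mt + si]] <- i1[singles_idx[si], , drop = FALSE]
  # leftovers round-robin over the multi records (already multi-key); a sex
  # flip is deterministic, so never stack two sex errors on one record
  if (length(leftover) > 0) {
    if (Mt == 0) stop("plan error: surplus instances but no multi-key records")
    cursor <- 0L
    for (li in leftover) {
      inst_class <- i1$attribute[li]
      placed <- FALSE
      for (step in seq_len(Mt)) {
        s <- (cursor + step - 1L) %% Mt + 1L
        if (inst_class == "sex" && any(slots[[s]]$attribute == "sex")) next
        slots[[s]] <- rbind(slots[[s]], i1[li, , drop = FALSE])
        cursor <- s
        placed <- TRUE
        break
      }
      if (!placed)
        stop("plan error: cannot place surplus sex errors on distinct records")
    }
  }
  slots
}

# concrete side choice for a name instance, preferring unbroken attributes
choose_side <- function(category, used) {
  scripts <- switch(category,
    typing = c("kanji", "kana"), omission = c("kanji", "kana"),
    name_change = c("kanji", "kana"), alias = c("kanji", "kana"),
    kanji_conversion = "kanji", variant_kanji = "kanji",
    misreading = "kana", missing_letter = "kana")
  sides <- if (category == "name_change") "family"
           else if (category == "alias") "first"
           else c("family", "first")
  for (s in sides) {
    if (!any(paste0(s, "_", scripts) %in% used)) return(s)
  }
  sides[1]
}

## ---- dataset specs and pair construction ----------------------------------

#' Specification of a linked dataset pair
#'
#' @param n_screening,n_registry,n_common table sizes and the size of the
#'   planted common subset (`n_common <= min(n_screening, n_registry)`).
#' @param label cancer-type label used for payload synthesis
#'   (`"colorectal"`, `"breast"` or anything else for generic payloads).
#' @param plan a [error_plan()]; `zero_error_plan()` for clean keys.
#' @param seed RNG seed; the pair is byte-identical for identical spec+seed.
#' @param sex optional forced sex for the whole population.
#' @return A `pddi_dataset_spec`.
#' @export
dataset_spec <- function(n_screening, n_registry, n_common,
                         label = "custom", plan = zero_error_plan(),
                         seed = 1L, sex = NULL) {
  stopifnot(inherits(plan, "pddi_error_plan"))
  if (n_common > min(n_screening, n_registry))
    stop("n_common exceeds a table size")
  if (plan$total > n_common)
    stop("plan error: more perturbed records than common records")
  structure(list(n_screening = as.integer(n_screening),
                 n_registry = as.integer(n_registry),
                 n_common = as.integer(n_common),
                 label = label, plan = plan, seed = as.integer(seed),
                 sex = sex),
            class = "pddi_dataset_spec")
}

#' Built-in dataset presets
#'
#' `colorectal`: 2000 screening rows vs 17,866 registry rows with 60 planted
#' common persons and the colorectal error plan. `breast`: 1048 vs 29,949
#' with 62 common persons, an all-female population (so sex is useless as a
#' key) and the breast error plan.
#'
#' @param preset `"colorectal"` or `"breast"`.
#' @param seed RNG seed.
#' @return A `pddi_dataset_spec`.
#' @export
dataset_preset <- function(preset = c("colorectal", "breast"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "colorectal") {
    dataset_spec(2000, 17866, 60, label = "colorectal",
                 plan = colorectal_error_plan(), seed = seed)
  } else {
    dataset_spec(1048, 29949, 62, label = "breast",
                 plan = breast_error_plan(), seed = seed, sex = "F")
  }
}

synthesize_payload <- function(role, n, label) {
  if (role == "screening") {
    res <- sample(c("positive", "negative"), n, TRUE, prob = c(0.07, 0.93))
    data.frame(
      screening_id = sprintf("S%06d", seq_len(n)),
      exam_date = format(as.Date("2021-01-01") +
                           sample.int(365L, n, TRUE) - 1L, "%Y-%m-%d"),
      test_result = res,
      risk_assessment = ifelse(res == "positive", "high", "low"),
      stringsAsFactors = FALSE)
  } else {
    codes <- switch(label,
      colorectal = c(sprintf("C18.%d", 0:9), "C19", "C20"),
      breast = sprintf("C50.%d", c(1:6, 8, 9)),
      "C80")
    names_lut <- switch(label,
      colorectal = "colorectal cancer", breast = "breast cancer", "cancer")
    data.frame(
      registry_id = sprintf("R%06d", seq_len(n)),
      icd10_code = sample(codes, n, TRUE),
      diagnosis_name = names_lut,
      diagnosis_date = format(as.Date("2021-06-01") +
                                sample.int(365L, n, TRUE) - 1L, "%Y-%m-%d"),
      stringsAsFactors = FALSE)
  }
}

#' Build a linked screening/registry dataset pair
#'
#' Generates one population, plants `n_common` persons in both tables,
#' perturbs the registry copy of the common records according to the error
#' plan (constructive assignment that hits every per-category count, the
#' multi-key count and the total exactly, verified by an audit pass that
#' recompares canonicalized attributes), shuffles the registry, and returns
#' both tables plus the ground-truth link table.
#'
#' @param spec a [dataset_spec()] or [dataset_preset()].
#' @return A `pddi_pair`: list with data frames `screening`, `registry`,
#'   `truth` (`person_uid`, `screening_row`, `registry_row`), the audit
#'   table `errors` (one row per injected error instance) and the `spec`.
#' @export
build_linked_pair <- function(spec) {
  stopifnot(inherits(spec, "pddi_dataset_spec"))
  lex <- load_lexicons()
  local_seed(spec$seed, {
    n_total <- spec$n_screening + spec$n_registry - spec$n_common
    pop <- generate_population(n_total, sex = spec$sex, lexicons = lex)
    screening <- pop[seq_len(spec$n_screening), ]
    registry_only <- pop[setdiff(seq_len(n_total), seq_len(spec$n_screening)),
                         , drop = FALSE]
    common_idx <- sort(sample.int(spec$n_screening, spec$n_common))
    common <- screening[common_idx, ]

    slots <- allocate_errors(spec$plan)
    perm <- sample.int(spec$n_common)  # slot i perturbs common record perm[i]
    # registry shuffle order drawn *before* error injection, so the
    # ground-truth link table does not depend on the error plan
    ord <- sample.int(spec$n_common + nrow(registry_only))
    perturbed <- common
    audit <- list()
    for (i in seq_along(slots)) {
      rec_i <- perm[i]
      row <- perturbed[rec_i, , drop = FALSE]
      used <- character(0)
      for (j in seq_len(nrow(slots[[i]]))) {
        category <- slots[[i]]$category[j]
        class <- slots[[i]]$attribute[j]
        side <- if (class == "name") choose_side(category, used) else "family"
        # retry until the targeted attributes differ from the *clean* record,
        # so a later instance can never silently revert an earlier one
        orig <- common[rec_i, , drop = FALSE]
        for (attempt in 1:30) {
          res <- apply_error_instance(row, category, class, side, lex)
          moved <- vapply(res$attrs, function(a)
            !identical(canonicalize_attribute(attribute_column(res$row, a), a),
                       canonicalize_attribute(attribute_column(orig, a), a)),
            TRUE)
          if (all(moved)) break
        }
        if (!all(moved))
          stop(sprintf("error operator %s/%s failed to perturb the record",
                       category, class))
        row <- res$row
        used <- union(used, res$attrs)
        audit[[length(audit) + 1L]] <- data.frame(
          person_uid = row$person_uid, category = category,
          attribute_class = class,
          attributes = paste(res$attrs, collapse = "+"),
          multi_key_slot = i <= spec$plan$multi_key,
          stringsAsFactors = FALSE)
      }
      perturbed[rec_i, ] <- row
    }
    audit <- if (length(audit)) do.call(rbind, audit) else
      data.frame(person_uid = character(0), category = character(0),
                 attribute_class = character(0), attributes = character(0),
                 multi_key_slot = logical(0))

    audit_errors(common, perturbed, spec$plan, audit)

    registry <- rbind(perturbed, registry_only)[ord, ]
    screening <- cbind(screening,
                       synthesize_payload("screening", nrow(screening),
                                          spec$label))
    registry <- cbind(registry,
                      synthesize_payload("registry", nrow(registry),
                                         spec$label))
    rownames(screening) <- rownames(registry) <- NULL
    truth <- data.frame(person_uid = common$person_uid,
                        screening_row = common_idx,
                        registry_row = match(common$person_uid,
                                             registry$person_uid),
                        stringsAsFactors = FALSE)
    structure(list(screening = screening, registry = registry, truth = truth,
                   errors = audit, spec = spec),
              class = "pddi_pair")
  })
}

# independent audit: recompare canonical attributes of clean vs perturbed
# common records and check every plan marginal
audit_errors <- function(clean, perturbed, plan, audit) {
  changed <- perturbed_attributes(clean, perturbed)
  n_changed <- vapply(changed, length, 0L)
  if (sum(n_changed > 0) != plan$total)
    stop(sprintf("plan audit failed: %d records perturbed, plan says %d",
                 sum(n_changed > 0), plan$total))
  if (sum(n_changed >= 2) != plan$multi_key)
    stop(sprintf("plan audit failed: %d multi-key records, plan says %d",
                 sum(n_changed >= 2), plan$multi_key))
  if (nrow(plan$items) == 0) return(invisible(TRUE))
  realized <- stats::aggregate(
    rep(1L, nrow(audit)),
    by = list(category = audit$category, attribute = audit$attribute_class),
    FUN = sum)
  want <- plan$items
  for (i in seq_len(nrow(want))) {
    got <- realized$x[realized$category == want$category[i] &
                        realized$attribute == want$attribute[i]]
    if (length(got) != 1 || got != want$count[i])
      stop(sprintf("plan audit failed for %s/%s: realized %s, plan %d",
                   want$category[i], want$attribute[i],
                   if (length(got)) got else 0L, want$count[i]))
  }
  invisible(TRUE)
}

# per-record list of canonical key attributes that differ between two
# equally-sized record tables
perturbed_attributes <- function(before, after) {
  stopifnot(nrow(before) == nrow(after))
  diff <- lapply(KEY_ATTRIBUTES, function(a)
    canonicalize_attribute(attribute_column(before, a), a) !=
      canonicalize_attribute(attribute_column(after, a), a))
  names(diff) <- KEY_ATTRIBUTES
  lapply(seq_len(nrow(before)), function(i)
    KEY_ATTRIBUTES[vapply(diff, `[`, TRUE, i)])
}

#' @export
print.pddi_pair <- function(x, ...) {
  cat(sprintf(
    "Linked dataset pair '%s': %d screening rows, %d registry rows, %d common persons\n",
    x$spec$label, nrow(x$screening), nrow(x$registry), nrow(x$truth)))
  cat(sprintf("  error plan: %d perturbed records, %d on multiple keys\n",
              x$spec$plan$total, x$spec$plan$multi_key))
  invisible(x)
}
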