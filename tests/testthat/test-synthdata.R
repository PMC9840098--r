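test_that("population generation is valid and reproducible", {
  a <- generate_population(10, seed = 99)
  b <- generate_population(10, seed = 99)
  expect_identical(a, b)
  big <- generate_population(10000, seed = 1)
  expect_identical(anyDuplicated(big$person_uid), 0L)
  # every birth date canonicalizes to ISO-8601
  iso <- canonicalize_attribute(big$birth_date, "birth_date")
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", iso)))
  # kanji and kana name fields are non-empty and paired
  expect_true(all(nchar(big$family_name_kanji) > 0))
  expect_true(all(nchar(big$family_name_kana) > 0))
  women <- generate_population(50, seed = 2, sex = "F")
  expect_true(all(women$sex == "F"))
  expect_error(generate_population(0), "positive")
})

test_that("error operators hit only their targeted attributes", {
  rec <- generate_population(1, seed = 5)

  res <- apply_error(rec, "missing_letter", "name", seed = 1)
  expect_identical(nchar(res$record$family_name_kana),
                   nchar(rec$family_name_kana) - 1L)
  expect_identical(res$record$family_name_kanji, rec$family_name_kanji)

  # misreading perturbs kana only; kanji byte-identical
  res <- apply_error(rec, "misreading", "name", seed = 2)
  expect_false(identical(res$record$family_name_kana, rec$family_name_kana))
  expect_identical(res$record$family_name_kanji, rec$family_name_kanji)

  # kanji conversion perturbs kanji only
  res <- apply_error(rec, "kanji_conversion", "name", seed = 3)
  expect_false(identical(res$record$family_name_kanji, rec$family_name_kanji))
  expect_identical(res$record$family_name_kana, rec$family_name_kana)

  # name change replaces both scripts of the family name
  res <- apply_error(rec, "name_change", seed = 4)
  expect_false(identical(res$record$family_name_kanji, rec$family_name_kanji))
  expect_false(identical(res$record$family_name_kana, rec$family_name_kana))
  expect_identical(res$record$first_name_kana, rec$first_name_kana)

  res <- apply_error(rec, "moving", seed = 5)
  expect_false(identical(res$record$address, rec$address))
  expect_identical(res$record$birth_date, rec$birth_date)

  res <- apply_error(rec, "typing", "birth_date", seed = 6)
  parsed <- canonicalize_attribute(res$record$birth_date, "birth_date")
  expect_false(identical(parsed, rec$birth_date))
  expect_true(grepl("^\\d{4}-\\d{2}-\\d{2}$", parsed))

  # person_uid survives every operator, and untouched attribute
  # combinations keep their compressed key
  for (cat in c("typing", "misreading", "variant_kanji", "address_format",
                "moving", "alias")) {
    res <- apply_error(rec, cat, seed = 7)
    expect_identical(res$record$person_uid, rec$person_uid)
    untouched <- setdiff(KEY_ATTRIBUTES, res$attrs)
    if (length(untouched) >= 2)
      expect_identical(make_key(res$record, untouched),
                       make_key(rec, untouched))
  }
  expect_error(apply_error(rec, "misreading", "address"), "does not target")
  expect_error(apply_error(rec, "fat_finger"), "unknown error category")
})

test_that("apply_error is exported with reproducible seeding", {
  rec <- generate_population(1, seed = 8)
  r1 <- apply_error(rec, "typing", "address", seed = 11)
  r2 <- apply_error(rec, "typing", "address", seed = 11)
  expect_identical(r1$record, r2$record)
})

test_that("built-in plans satisfy every marginal exactly", {
  # independent recount: compare canonicalized attributes of the clean
  # screening copy against the perturbed registry copy, per common person
  check_pair <- function(pair, plan) {
    clean <- pair$screening[pair$truth$screening_row, ]
    dirty <- pair$registry[pair$truth$registry_row, ]
    changed <- pddi:::perturbed_attributes(clean, dirty)
    n_changed <- lengths(changed)
    expect_identical(sum(n_changed > 0), plan$total)
    expect_identical(sum(n_changed >= 2), plan$multi_key)
    got <- stats::aggregate(
      rep(1L, nrow(pair$errors)),
      by = list(category = pair$errors$category,
                attribute = pair$errors$attribute_class), FUN = sum)
    for (i in seq_len(nrow(plan$items))) {
      expect_identical(
        got$x[got$category == plan$items$category[i] &
                got$attribute == plan$items$attribute[i]],
        plan$items$count[i])
    }
  }
  pc <- build_linked_pair(dataset_preset("colorectal", seed = 1))
  check_pair(pc, colorectal_error_plan())
  pb <- build_linked_pair(dataset_preset("breast", seed = 1))
  check_pair(pb, breast_error_plan())
  expect_true(all(pb$screening$sex == "F"))
})

test_that("infeasible plans are rejected with the violated marginal", {
  items <- data.frame(category = "typing", attribute = "sex", count = 5L)
  expect_error(build_linked_pair(
    dataset_spec(100, 100, 10,
                 plan = error_plan(items, multi_key = 5, total = 5))),
    "plan error")
  expect_error(error_plan(items, multi_key = 6, total = 5), "plan error")
  expect_error(error_plan(data.frame(category = "misreading",
                                     attribute = "sex", count = 1L), 0, 1),
               "cannot target")
  expect_error(dataset_spec(10, 10, 20), "n_common")
  expect_error(dataset_spec(10, 10, 5, plan = error_plan(
    data.frame(category = "moving", attribute = "address", count = 6L),
    0, 6)), "plan error")
})

test_that("pairs are byte-identical for identical spec and seed", {
  spec <- dataset_spec(80, 200, 40, plan = breast_error_plan(), seed = 77)
  p1 <- build_linked_pair(spec)
  p2 <- build_linked_pair(spec)
  expect_identical(p1$screening, p2$screening)
  expect_identical(p1$registry, p2$registry)
  expect_identical(p1$truth, p2$truth)

  d1 <- file.path(tempdir(), "pair1"); d2 <- file.path(tempdir(), "pair2")
  write_pair(p1, d1); write_pair(p2, d2)
  for (f in c("screening.csv", "registry.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("ground truth is invariant under the error plan", {
  plan <- error_plan(
    data.frame(category = c("misreading", "moving", "typing"),
               attribute = c("name", "address", "birth_date"),
               count = c(4L, 3L, 3L)),
    multi_key = 2, total = 8)
  zero <- build_linked_pair(dataset_spec(80, 200, 25, seed = 31))
  errs <- build_linked_pair(dataset_spec(80, 200, 25, plan = plan, seed = 31))
  expect_identical(zero$truth, errs$truth)
  # and the registry copies of common persons are perturbed, screening clean
  expect_identical(zero$screening[zero$truth$screening_row,
                                  "family_name_kana"],
                   errs$screening[errs$truth$screening_row,
                                  "family_name_kana"])
})
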