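# pddi — privacy-preserving distributed data integration for record linkage

`pddi` is an R toolkit for linking person records held by mutually
distrusting institutions — the motivating case is matching a municipal
cancer-screening table against a prefectural cancer-registry table in a
country without a national identification number — **without any party ever
seeing another party's plaintext identifiers**. It also ships the full
evaluation apparatus around such a linkage: a synthetic generator for linked
dataset pairs with realistic Japanese identifier errors, matching-accuracy
scoring, and an analytic model that converts matching accuracy into the
*apparent* accuracy of the screening programme itself.

## The protocol

Institutions agree on a matching-key combination (subsets of family/first
name in kanji and kana, birth date, sex, optionally address). Each
institution then:

1. canonicalizes the attributes (Unicode NFKC, ISO dates, M/F/U sex codes),
   compresses each key to an irreversible SHA-256 digest, encodes its key
   set in a Bloom filter (sized so the per-key false-positive probability is
   ≤ 10⁻⁹), and encrypts the filter element-by-element with **lifted
   ElGamal** under a joint public key h = g^(Σᵢ xᵢ) whose secret is
   additively shared across all institutions;
2. a semi-honest server sums the encrypted filters homomorphically — it
   holds no key material and can decrypt nothing;
3. the institutions exchange partial decryptions c₁^xᵢ, decode the summed
   filter exactly (the message space is bounded by the institution count, so
   the discrete log is a table lookup), and learn exactly which of their own
   keys every institution holds; payload rows of those keys are
   hybrid-encrypted to the client and tagged with an anonymous link id (a
   keyed digest under an institutions-only secret);
4. the server groups payload rows by link id and forwards them to the
   client, which receives the integrated data but no key material.

Because the encryption is probabilistic, equal keys encrypt to different
ciphertexts, so neither the server nor any institution can run a dictionary
attack on the transcript — the failure mode of naive hashed-identifier
matching.

## The misclassification model

When the screening outcome (cancer within follow-up) is ascertained through
a linkage with matching sensitivity Se_m and specificity Sp_m, the apparent
screening accuracy at prevalence p is

    Se' = [p·Se_m·Se_s + (1−p)(1−Sp_m)(1−Sp_s)] / [p·Se_m + (1−p)(1−Sp_m)]
    Sp' = [p(1−Se_m)(1−Se_s) + (1−p)·Sp_m·Sp_s] / [p(1−Se_m) + (1−p)·Sp_m]
    PPV' = [p·Se_s·Se_m + (1−p)(1−Sp_s)(1−Sp_m)] / [p·Se_s + (1−p)(1−Sp_s)]

with two exact identities: perfect matching sensitivity leaves the apparent
specificity untouched, and perfect matching specificity leaves the apparent
sensitivity untouched. For rare outcomes the estimates are dramatically more
sensitive to Sp_m than to Se_m — the central design message for choosing
matching keys. Companion operators propagate the same misclassification into
cohort risk ratios (`apparent_cohort_rr`) and case-control odds ratios
(`apparent_case_control_or`).

## Worked example

```r
library(pddi)

# a synthetic screening/registry pair: 2000 vs 17,866 rows, 60 planted
# common persons, 51 of them carrying identifier errors (25 on >= 2 keys)
pair <- build_linked_pair(dataset_preset("colorectal", seed = 1))
pair
#> Linked dataset pair 'colorectal': 2000 screening rows, 17866 registry rows, 60 common persons
#>   error plan: 51 perturbed records, 25 on multiple keys

# run the encrypted linkage on birth date + first name (kana)
sess <- run_session(list(screening = pair$screening, registry = pair$registry),
                    combo = c("birth_date", "first_kana"), seed = 1)
sess
#> PDDI session: 2 institutions, combo {first_kana, birth_date}, 64 intersection group(s)
#>   transcript: 9 messages, 112507198 bytes total

# score it against the planted ground truth
sp <- session_pairs(sess, list(screening = pair$screening, registry = pair$registry))
acc <- accuracy(score_matches(
  data.frame(screening_row = sp$row_screening, registry_row = sp$row_registry),
  pair$truth, nrow(pair$screening)))
acc
#> matching sensitivity 66.67%, specificity 98.71%

# what would that linkage do to a 90%/90% screening programme?
apparent_screening_accuracy(0.90, 0.90, acc$sensitivity/100, acc$specificity/100)
#> Apparent screening accuracy (matching Se 66.67%, Sp 98.71%, prevalence 0.007757):
#>   sensitivity: 33.02% (true 90%)
#>   specificity: 89.79% (true 90%)
#>   PPV:         5.59% (true 6.6%)
```

The last block is the point of the package in three lines: a linkage that
misses a third of true pairs *and* mislinks 1.3% of non-pairs makes a 90%
sensitive screening test look 33% sensitive, because the outcome is rare.
`sweep_combinations(pair)` scores all 57 attribute combinations at once
(in seconds, via the plaintext fast path that the encrypted path provably
agrees with), and `scenario_table()` prints the built-in 16-row grid of
apparent-accuracy scenarios.

A command-line interface wraps the same functions:

```sh
pddi generate --preset colorectal --seed 7 --out pair/
pddi run --screening pair/screening.csv --registry pair/registry.csv \
         --combo birth_date,first_kana --out session/
pddi sweep --pair pair/ --mode plaintext
pddi propagate --table3
```

## Scope and caveats

- Honest-but-curious security model; no malicious-adversary hardening, no
  elliptic-curve backend. `production` mode uses a 2048-bit MODP group;
  `test` mode uses a deliberately tiny group for fast simulation and offers
  no security.
- Exact matching only: the package deliberately implements no phonetic or
  probabilistic matching, so matching sensitivity is bounded by the fraction
  of error-free keys.
- The synthetic generator's lexicons are small illustrative tables; they
  emulate error *mechanisms* (homophone kanji swaps, kana misreadings,
  format variants, renaming, moving) rather than any real population.

See the methods vignette (`vignettes/pddi-methods.Rmd`) for the model's
assumptions, parameter choices and limitations.
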