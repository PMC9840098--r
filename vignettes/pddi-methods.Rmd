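---
title: "Methods: privacy-preserving record linkage and its downstream accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: privacy-preserving record linkage and its downstream accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pddi)
```

## The problem

Epidemiological surveillance often requires linking two person-level tables
held by institutions that are not allowed to pool them: the motivating
setting is assessing cancer-screening accuracy, where the screening result
lives with a municipality and the outcome (a cancer diagnosis within one or
two years) lives in a prefectural registry. Without a national identifier,
linkage must run on personal attributes — names in two scripts, birth date,
sex, address — and those attributes must not leave their institutions in
plaintext. `pddi` implements both halves of the methodological problem:

* a **private set intersection** protocol that reveals, to the data holders
  only, exactly which matching keys all institutions share, and integrates
  the payload rows attached to those keys for a client; and
* the **evaluation machinery** that answers "was the linkage good enough?":
  synthetic error-laden test pairs, matching sensitivity/specificity
  scoring, and the analytic propagation of linkage misclassification into
  apparent screening accuracy and epidemiological effect estimates.

## Protocol model and assumptions

All parties are *honest-but-curious*: they follow the protocol but would
read anything readable. There are three roles — data-holding institutions
(≥ 2), one computation server, and a client that receives the integrated
result (in practice one institution doubles as the client). The protocol's
privacy contract, realized mechanically and checked by the test suite on
every transcript:

* no message body ever contains a canonical attribute value or a bare key
  digest;
* the server's view consists solely of ciphertexts and their homomorphic
  sums; it holds no decryption capability;
* the client receives payload rows grouped by an *anonymous link id* — a
  keyed digest of the compressed key under a secret shared only among the
  institutions — and never the keys themselves.

### Cryptosystem

The element encryption is lifted (exponential) ElGamal over a Schnorr
group: a message $m$ becomes $(g^r,\; g^m h^r)$ under the joint key
$h = g^{\sum_i x_i}$, each institution holding one additive share $x_i$.
This choice follows from three requirements: ciphertexts must be
*probabilistic* (equal plaintexts encrypt differently, defeating dictionary
attacks on the transcript), *additively homomorphic* (the server sums
filters without decrypting), and decryptable only with *all* shares
($\prod_i c_1^{x_i}$ is required to strip the mask). Messages are tiny —
per-position Bloom counts bounded by the institution count — so the final
discrete logarithm is an exact table lookup over $g^0 \dots g^n$; there is
no decoding tolerance anywhere.

Two parameter modes exist. `production` uses the 2048-bit RFC 3526 MODP
group (subgroup order 2047 bits; scalars drawn from the OS entropy pool).
`test` uses a 31-bit safe-prime group with the seedable R RNG; it offers no
security and exists so that simulations encrypting hundreds of thousands of
filter positions run in seconds. The mode is carried inside every parameter
object, and the arithmetic layer transparently uses native 64-bit modular
arithmetic for small groups and multiprecision arithmetic (Knuth division,
square-and-multiply) for production-size ones; both paths are tested against
an independent big-integer oracle.

Key generation is simulated centrally and the shares handed out in-process;
a distributed key-generation ceremony is an implementation concern outside
this package's scope.

### Bloom encoding

Each institution's set of compressed keys is encoded in a bit array of
`m_bits` bits with `k_hashes` double-hashed positions per key
(`h1 + j·h2 mod m`, both hashes taken from disjoint 48-bit slices of a
salted SHA-256). The elementwise sum of all institutions' filters equals
`n` at every position of a key held by everyone — no false negatives, by
construction. False positives arise only from filter saturation;
`bloom_dimension()` sizes filters so the per-key false-positive probability
is at most $10^{-9}$ at the declared capacity ($m = \lceil -n \ln f /
\ln^2 2\rceil$, $k = \mathrm{round}(m/n \cdot \ln 2)$), which makes protocol
output coincide with exact set intersection for any realistic session; the
test suite asserts exact agreement with a brute-force intersection oracle
over hundreds of randomized sessions. All institutions share one filter
shape (the largest declared capacity), since summation requires congruent
vectors. The position salt is a per-session secret shared by the
institutions and withheld from the server, so the server cannot precompute
position patterns of candidate identities.

A deliberate consequence of per-position *bit* encryption: the summed
filter decodes to position counts in `[0, n]`, and any count above `n`
aborts the session as a corrupted transcript.

### Matching keys

Exact matching is the package's matching semantics — two records link when
*all* attributes of the chosen combination agree after canonicalization.
Canonicalization is the minimum that makes exact matching meaningful across
institutions: Unicode NFKC (folding full-width digits and half-width
katakana), whitespace stripping, ISO-8601 birth dates, M/F/U sex codes.
Missing values canonicalize to the empty string so that two records missing
the same field can still agree on it. Unparseable dates raise an error
carrying the offending raw value rather than silently producing an
unmatchable key. Compressed keys are SHA-256 digests of the canonical
values joined in a fixed attribute order with a U+001F separator.

Seven attributes are modelled; the default matching set excludes address
(unstable under moves and format variants), and combinations of fewer than
two attributes are rejected outright — single-attribute matching floods the
linkage with false positives. With six attributes there are 57 usable
combinations; dropping sex (meaningless in a single-sex screening
population) leaves 26.

## The synthetic data generator

`build_linked_pair()` emulates the study conditions the evaluation targets:
a screening table and a much larger registry table with a planted common
subset whose registry copies carry identifier errors. The built-in presets
fix the scenario sizes — 2000 vs 17,866 rows with 60 common persons
(`colorectal`), 1048 vs 29,949 with 62 (`breast`, all-female population) —
and error plans that perturb 51 of 60 common records (25 on two or more
keys) and 36 of 62 (14 multi-key) respectively. Error rates that high are
deliberately pessimistic: they stress the linkage far beyond the ≤ 10–15%
error prevalence typical of real registries, so measured sensitivities are
floor estimates, not forecasts.

An error plan is a table of (category, attribute-class, record-count) rows
plus two global marginals: the number of perturbed records and the number of
records left unmatched on ≥ 2 canonical attributes. The allocator satisfies
all marginals *exactly* by construction — spanning error events first, then
distinct-attribute pairs for the remaining multi-key records, then single
errors, with surplus instances folded into already-multi-key records — and
an independent audit pass recompares every canonical attribute of the clean
and perturbed copies and aborts on any deviation. Infeasible plans fail
loudly with the violated marginal.

Ten error categories are modelled, each with the mechanism a Japanese
registry would actually exhibit: character typos (which, for names, pass
through IME conversion and therefore corrupt *both* the kana and the kanji
form), homophone kanji-conversion errors (kanji changes, reading intact),
misreadings (kana changes, kanji intact), dropped characters, omitted name
or address components, variant-kanji orthography, address format reflows
(including full-width digit forms), renaming on marriage, aliases, and
moves. Categories that replace a whole name (and name-typos and omissions)
span both scripts — this is what lets a *single* error event leave a record
unmatched on two keys, and it is the only reading under which the built-in
plans' marginals are simultaneously satisfiable; the audit enforces the
realized counts regardless. Substitution material (name lexicons, homophone
and variant-kanji tables, place names) ships as small editable TSV files;
they are synthetic and illustrative, so the generator reproduces error
*mechanisms*, not the linguistic distribution of any real population — a
deliberate limitation to keep in mind when reading absolute accuracy
numbers off synthetic pairs.

Determinism: a pair is byte-identical for identical spec and seed, and the
ground-truth link table is drawn before error injection, so it is invariant
under the error plan.

## Scoring a linkage

The screening table is the reference. Per screening record: matched to its
true counterpart → true positive; counterpart exists but was not matched →
false negative; matched to ≥ 1 wrong person → (also) one false positive;
non-common and unmatched → true negative. A record matched to both its
counterpart and a stranger therefore contributes one tp *and* one fp — the
bookkeeping is recorded alongside every run so alternative tallies can be
recomputed from the stored pairs. Matching sensitivity is
$100\,tp/(tp+fn)$, specificity $100\,tn/(tn+fp)$, printed to two decimals
with half-up rounding (base R's banker's rounding would disagree with the
conventional presentation on exact ties).

`sweep_combinations()` scores every combination through a pair-free
count-based scorer (equivalent to scoring the all-pairs join, but linear
even for near-degenerate combinations that match almost everything); the
full protocol path is available per combination and must produce identical
counts, which the suite asserts.

## The misclassification model

The propagation formulas (see the package README or `?apparent_screening_accuracy`)
follow from one assumption: linkage errors are independent of the screen
result, so linkage acts as a non-differential misclassifier of the outcome.
Each apparent quantity is then a ratio of expected cell counts of the
disease × screen × linked 2×2×2 table; cohort size cancels. The test suite
checks the closed forms against an explicit expected-count cross-tabulation
at $N = 10^7$ for 100 random scenarios (agreement to $10^{-10}$), and the
boundary identities symbolically across a parameter grid.

Defaults: prevalence 775.7 per 100,000 person-years (a national average
all-cancer incidence), screening scenarios 90%/90% and 60%/90%. The built-in
`scenario_table()` grid crosses these with eight matching assumptions —
specificity pinned at 100% while sensitivity steps 90/85/50%, sensitivity
pinned at 100% while specificity steps 99.99/99.90/99.80%, plus the two
experimentally observed pairs (88.71%, 99.80%) and (82.26%, 100%). Identity
cells (where a perfect matching margin provably leaves the estimate
unchanged) print `NA`, except in the experimental rows, which always show
both estimates. Percentages are reported to two decimals, true PPV to one,
half-up.

The same misclassification operator applied to exposure or outcome
ascertainment gives the cohort and case-control results: apparent incidence
$I' = I\,Se_m + (1-I)(1-Sp_m)$ in each arm, from which matching sensitivity
cancels out of a risk ratio entirely (attenuation is driven by matching
specificity alone), and apparent exposure prevalence transforms identically
in both arms of a case-control design, shrinking odds ratios toward 1 and
leaving a null association null. Both operators reject degenerate inputs
(rates at 0 or 1) rather than returning infinities.

## Numerical and design choices

* **Rounding** is half-up everywhere a percentage is printed, two decimals
  (one for true PPV), implemented with a small noise guard so binary
  representation error cannot flip a tie.
* **Decoding** has no tolerance: a summed-filter element that matches no
  entry of $g^0..g^n$ is an error, never a nearest value.
* **Tie/duplicate handling**: several registry rows sharing one key all
  join the link group, with per-source multiplicity preserved, so duplicate
  registrations are visible downstream rather than silently collapsed.
* **Degenerate sessions**: empty institutions produce all-zero filters and
  empty results; an empty intersection is an empty (not absent) result.
* **Problem sizes in the suite** were chosen to exercise every code path
  while keeping the default run in tens of seconds: 50 randomized protocol
  sessions with 2–4 institutions and up to ~50 keys each, one full
  2¹⁰-record encrypted run compared record-for-record with the plaintext
  path, and full-size (2000 × 17,866 and 1048 × 29,949) generator builds
  and 57-combination sweeps, which run in seconds via the plaintext path.

## Known limitations

* Exact matching only; no phonetic, edit-distance or probabilistic
  linkage. Matching sensitivity on a pair is therefore bounded above by the
  fraction of common records whose keys in the chosen combination are
  error-free, and the package makes that bound inspectable rather than
  trying to beat it.
* Honest-but-curious adversaries; no protection against parties that inject
  malformed ciphertexts beyond transcript-consistency checks.
* Transport is an in-process simulation of all roles (with transcripts that
  record every message and its byte size); wall-clock, memory and network
  benchmarking of a distributed deployment is hardware-bound and out of
  scope.
* The generator's payload fields (test results, diagnosis codes, dates) are
  decorative and uniformly random; they exist to exercise payload-carrying
  machinery, not to model clinical reality.
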