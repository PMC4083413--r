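---
title: "Anonymizing SNV aggregation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing SNV aggregation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snvblur` turns a cohort of per-sample VCFs plus phenotype metadata into
a shareable, sites-only VCF from which individuals cannot be
re-identified, together with an encrypted linkage file that only the
submitter can open. This vignette is the package's own account of the
method: what each step assumes, which knobs matter, what the synthetic
cohort generator does and does not emulate, and the decisions taken
where the design was genuinely open.

## The data model

An SNV is identified everywhere by the four-tuple `chrom:pos:ref:alt`
(1-based VCF coordinates, single upper-case bases, `ref != alt`). Only
het and hom-alt genotypes are stored; homozygous-reference is the
implicit default. Indels and symbolic alleles are skipped and counted,
never an error: the scope of the method is SNVs. Multi-allelic VCF lines
are split into one record per SNV alternate; a genotype referencing
allele *j* makes the sample a carrier of that alternate only. Phase
separators are ignored.

Sample metadata travels in an INI file: a `[global]` section
(trait, PI, contact, all acting as defaults) and one `[sample:<ID>]`
section per sample (`vcf`, `status`, `gender`, `platform`, `enrichment`,
`hpo_present`, `hpo_absent`; HPO lists are `;`-separated IDs matching
`HP:` + 7 digits). Trait, status and contact are mandatory; everything
else is optional.

## Step 1 — metadata suppression to k-anonymity

The released attribute tuple of a sample is
(trait, HPO present, HPO absent, gender, platform, enrichment), with
unset values shown as `unknown`. The requirement is that every released
tuple occurs in at least `k` samples (`k = 2` by default, configurable
upward): a unique combination would let an attacker attach all of a
patient's variants to an identifiable description.

Suppression is greedy. While a violating tuple exists, the smallest
violating group (ties broken deterministically by tuple string) loses
one attribute — for *all* of its members, so released values stay
consistent — in the fixed priority order

> enrichment → platform → gender → HPO sets,

chosen to keep the clinically informative HPO terms longest. When a
violating group is already down to its bare trait, the same deletion is
applied to its trait-peers (the samples sharing its trait), since
otherwise the group could never merge with anything; the procedure fails
only when a trait itself occurs fewer than `k` times, which no amount of
attribute deletion can repair (trait and patient/control status are
never suppressed). A cohort-unique HPO set is cleared entirely rather
than generalized to parent terms — ontology-walking generalization is a
different algorithm and out of scope. Every deletion is logged
(`sample_id`, attribute, reason), exportable as JSON lines.

Two properties follow by construction and are enforced by tests:
suppression never *adds* information (each output attribute equals the
input or is unknown), and it is idempotent.

## Step 2 — fragmentation and the encrypted linkage

Each sample's calls are partitioned into `n_subsamples` fragments
(default 5). If fragments were near-equal in size, a group of linked
sub-samples could be recognized by its size signature and the sample
reconstructed; the assignment is therefore deliberately non-uniform.
Per sample, a weight vector is drawn once from the flat (symmetric,
concentration-1) law on the probability simplex — all weight vectors
equally likely — and each SNV is assigned independently with those
weights. At `k = 5` this law gives an expected size coefficient of
variation around `sqrt((k-1)/(k+1)) ≈ 0.82`; the test suite asserts the
mean CV exceeds 0.25. The weight-law identifier is recorded in the
configuration for reproducibility. Sub-sample ids are random 128-bit hex
tokens drawn from the seeded RNG: reproducible under a seed, but
carrying no information about the source sample.

The sample ↔ sub-sample map — including each sample's complete call
list, so that withdrawal can also repair blurred records — exists only
in the linkage file: JSON, encrypted with AES-256-CBC and authenticated
with HMAC-SHA256 (encrypt-then-MAC), both keys derived from the
passphrase with the bcrypt PBKDF (16 rounds, random 16-byte salt). The
scheme identifier and KDF parameters are stored in a plaintext header;
a wrong passphrase or a single flipped bit fails authentication before
any plaintext is produced. Authenticated modern encryption was chosen
deliberately over legacy single-pass ciphers: an unauthenticated
linkage file would undermine the very privacy goal it protects.

## Step 3 — the median-adaptive rare rule

`freq(SNV)` is the number of samples carrying at least one alternate
allele at the site, irrespective of genotype (het and hom both count 1).
An SNV is rare — and blurred — iff

```
freq(SNV) <= factor * median(freq),   factor = 1.5
```

The median is robust against the dominating singleton mass, which is
exactly the class that must be blurred: a patient is trivially
identified by their singletons. Numerical choices, all covered by
tests:

* `<=` at exact equality (configurable to strict `<` via `rare_cmp`);
  with integer counts and usually non-integer thresholds this matters
  only when `factor * median` is an attained integer.
* The median of an even-length multiset is the mean of the two middle
  values.
* Counts, not proportions, feed the median — equivalent for the rare
  test at fixed cohort size.
* Degenerate input: if all counts are equal (`k` for every site) then
  `k <= 1.5 k` always holds and the whole store is blurred; a 2-sample
  cohort with one shared SNV yields threshold 3 and a fully blurred
  store. This is forced by the formula, not an error.

Blurred records keep locus, alleles, a trait summary aggregated to
`label|count` pairs over carriers (never per sample) and the submitter
contact; they lose sub-sample ids and het/hom counts. Raising `factor`
can only grow the blurred set (monotonicity, tested).

Withdrawal (`remove_sample`) decrypts the linkage, deletes every
contribution of the sample — including decrementing carrier and trait
counts inside blurred records, which the public store alone could not
support — and drops empty records. The threshold is deliberately *not*
recomputed: re-thresholding could move a published blurred record back
to unblurred, re-attaching linkage that was never public. The released
tuple table is kept as the historical echo of the original release.

## The synthetic cohort generator

Real exome cohorts show an occurrence-count spectrum with a strong
singleton excess and a secondary mass of variants shared by nearly
everyone. The generator draws each site's count `k` (in `1..n`) i.i.d.
from the mixture

```
f(k) = (1 - w) * k^(-alpha) / Z  +  w * Uniform{ceil((1-band)*n) .. n}
```

with defaults `alpha = 1`, `w = 0.10`, `band = 0.10`, then picks `k`
carriers uniformly without replacement and makes each carrier hom-alt
with probability `p_hom = 1/3`. The defaults were calibrated
analytically, once, so that at `n = 50` the spectrum simultaneously
reproduces the three features expected of a 50-exome set: a
singleton:all-carrier ratio near 10 (analytic value
`f(1)/f(50) = 9.68`), a median count of 7 — hence a rare threshold of
10.5 whose largest rare count, 10, is 20 % of samples — and, at the
default 140,000 sites, about 41,000 SNVs per sample, the scale of a
human exome. At `n = 40` and `n = 60` the same defaults put the
threshold at 9 and 10.5–12, inside the 8–12 band expected for
default-factor aggregation. Metadata is synthesized with trait groups
assigned in blocks of at least two samples (so the cohort is always
k-anonymizable) and randomized gender/platform/enrichment so the
suppression step has real work.

What the generator does *not* emulate: linkage disequilibrium between
sites, per-sample rate variation, population structure, genotyping
error, or realistic genome coordinates (sites sit on a synthetic
per-chromosome grid). Carriers are exchangeable. Passing tests
therefore demonstrate the *algorithms* — partitioning, counting,
thresholding, suppression — under a realistic *marginal* spectrum, not
robustness to correlated real-world data. The identification
experiment in particular inherits this: in real exomes shared haplotype
blocks could make sub-samples of related individuals more similar than
exchangeability predicts.

## Evaluation diagnostics

* `unblurred_ratio` reports the surviving fraction over genotype
  *records* (carrier-count sums) by default: the definition of "data"
  under which the common variants that dominate released genotype mass
  count proportionally. The per-*site* variant is also computed, since
  the alternative reading is defensible; both are emitted by
  `ratio_curve`.
* `ratio_curve` exploits the fact that the blur decision depends only on
  the count multiset: the ratio is computed directly from simulated
  spectra without materializing genotypes, and a unit test pins its
  equality with the full simulate → aggregate → `unblurred_ratio` path.
  The expected curve grows with cohort size and saturates; the exact
  plateau level depends on the cohort's frequency spectrum, so the test
  suite asserts the shape (monotone growth, shrinking gains), not a
  literal plateau value.
* `overlap_assessment` runs the adversary: given a probe sample's full
  SNV set, score every visible sub-sample by shared count, containment
  and Jaccard similarity. Own sub-samples have containment exactly 1
  (they are subsets of the probe), so containment is useless to an
  attacker who does not know the answer; Jaccard is the discriminating
  metric and is used for the headline top-K identification precision
  (K = number of own sub-samples). "Not identifiable" is
  operationalized as mean top-K precision below 0.8 across seeds on a
  10-sample cohort — a reconstruction of the qualitative claim, not a
  hypothesis test.

## The aggregated VCF dialect

The output is a sites-only VCF 4.2 (sub-samples are not fixed-width
columns, and blurred rows have no genotypes, so sample columns would be
wrong): all information lives in `GB*` INFO keys (`GBN`, `GBCAR`,
`GBHET`, `GBHOM`, `GBTRAIT`, `GBSUBS`, `GBCLASS`, `GBBLUR`,
`GBCONTACT`), declared in header meta-lines together with cohort-level
metadata (phenotype-class definitions, released tuples with counts, the
sub-sample → class map, and the threshold echo). Free-text values are
percent-encoded so no `;,=|` or whitespace can corrupt the INFO field.
Records are sorted by (chrom, pos, ref, alt) with numeric-aware
chromosome order. `read_aggregated_vcf(write_aggregated_vcf(s))` is
field-exact, and `validate_aggregated_vcf` checks files for malformed
lines, blurred records that still carry linkage or genotype counts,
carrier counts inconsistent with listed genotypes, duplicate keys and
ordering — as report entries, never errors.

## Queries

Search terms are classified by syntax: `chrom:pos` (a leading `chr` is
tolerated), `rs` IDs (the `.` sentinel never matches), and gene symbols
resolved against a user-supplied interval file. For BED input a
position hits an interval when `start <= pos < end` on the printed
coordinates (so a variant at the printed start matches and one at the
printed end does not); GFF intervals are 1-based closed. Allele
frequency counts het carriers once and hom carriers twice over `2n`
chromosomes; genotype frequencies use all `n` samples as denominator,
with the carrier count reported alongside. Blurred records return the
submitter contact and no frequencies. External reference frequencies
are accepted as a local TSV keyed by `chrom, pos, ref, alt` — no
network access anywhere in the package.

## Problem sizes used by the test suite

The distribution-level checks run at the generator's native scale
(50-sample, 140,000-site cohorts; threshold range over n = 40/50/60 at
140,000 sites). The ratio curve uses 12,000 sites per replicate — the
ratio is a function of the count distribution, so site count only sets
sampling noise — and the identification experiment uses 20 seeds of
10-sample cohorts at 40,000 sites, the identification statistic being
likewise invariant in site count. These sizes are the package's own
choices, balancing Monte-Carlo error against test runtime.

## Known limitations

* k-anonymity of the released tuples does not imply l-diversity or
  t-closeness; a class's trait is public by design.
* Duplicate submissions are not detected; re-aggregating overlapping
  cohorts inflates counts.
* No variant quality scores are carried; the intended workflow is to
  contact the submitter for quality details.
* Consent withdrawal repairs counts but cannot reverse information
  already disclosed in earlier store versions.
* No liftover, no normalization of complex variants, no BCF.
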