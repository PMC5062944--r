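---
title: "Privacy-preserving GWAS statistics and genome distances: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving GWAS statistics and genome distances: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genocrypt)
```

## Scope and threat model

genocrypt implements, end to end, the two classic privacy-preserving
genome-analysis settings of the secure-computation benchmark literature:

1. **Secure outsourcing.** A data owner with limited resources stores and
   analyses a case/control genotype panel on an untrusted cloud server.
   The server is *semi-honest* (honest-but-curious): it follows the
   protocol faithfully but inspects every message it sees. The owner
   encrypts the data under an additively homomorphic cryptosystem; the
   server computes on ciphertexts only and can decrypt nothing.
2. **Secure collaboration.** Two institutions jointly compute statistics
   over the union of their private datasets (a horizontally partitioned
   cohort, or one genome each) without exchanging the data. Messages on
   the wire must reveal nothing beyond the agreed outputs.

Malicious adversaries, garbled circuits, full/levelled homomorphic
encryption and three-server secret sharing are deliberately out of
scope: the semi-honest two-party model with an 80-bit security floor is
the setting this toolkit targets, and the heavier machinery changes the
engineering entirely.

## The plaintext contract

Everything secure in this package is measured against one plaintext
oracle, so the statistics must be defined exactly.

**Allele counts.** At each SNP site, a non-missing sample of dosage
$k \in \{0,1,2\}$ contributes $k$ alternate and $2-k$ reference alleles
to its group; missing samples are excluded from that site's denominators
(complete-allele analysis). The minor allele is called on the **combined
cohort** — per-group minor alleles can disagree, which would make the
2×2 table ill-defined.

**MAF.** With case minor/major counts $a, b$ and control counts $c, d$,
$\mathrm{maf} = \min(p, 1-p)$, $p = (a+c)/N$, $N = a+b+c+d$; always in
$[0, 0.5]$.

**Association test.** The allelic Pearson chi-square on the 2×2 allele
table, one degree of freedom, no continuity correction:
$$\chi^2 = \frac{N\,(ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}.$$
The 2×3 genotypic test is a possible alternative reading of
"chi-square test" in this setting; the allelic form is the standard
reading in MAF-centred benchmark tasks, and keeps the
secure arithmetic purely integer-rational. Dropping the Yates correction
is likewise deliberate: the statistic then depends on the four integer
counts only, so a secure protocol that reproduces the counts reproduces
the statistic bit for bit. A zero marginal makes the statistic undefined
and is reported as `NA`, never silently as 0. p-values come from the
1-df chi-square survival function and are a convenience output, not part
of the equality contract.

## Secure outsourcing: Paillier aggregation

The Paillier cryptosystem is additively homomorphic:
$E(m_1)\,E(m_2) \bmod n^2 = E(m_1 + m_2)$ and
$E(m)^k = E(km)$. We use the simplified $g = n + 1$ variant
($E(m) = (1 + mn)\,r^n \bmod n^2$), which is standard, faster, and
equivalent in security. Key generation draws equal-size probable primes
(Miller–Rabin error well below $2^{-80}$) with the top two bits set so
the modulus has exactly the requested width.

The protocol: the owner encrypts, for every (sample, site) pair, the
alternate-allele dosage and twice the non-missing indicator; the server
— an object that structurally cannot hold a private key — homomorphically
sums them into four ciphertexts per site (case-alt, case-total,
control-alt, control-total); the owner decrypts only these aggregates
and finishes MAF and $\chi^2$ in the clear. Finishing locally is the
sanctioned division of labour in this setting: the aggregate counts are
exactly what the owner is entitled to learn. Per-sample encryption (not
encrypted local counts) is what makes this genuine outsourcing of both
storage and computation.

Parameters: the 80-bit security floor maps to a 1024-bit modulus by the
standard NIST-era equivalence; `paillier_keygen()` refuses less unless
an explicit `allow_insecure` flag requests small, loudly-labelled test
keys (used for fast CI-style runs, including most of this package's own
test suite; a 1024-bit spot check runs alongside). Aggregate counts are
bounded by twice the sample count, so modulus overflow is unreachable —
asserted anyway. Ciphertext packing/batching schemes are out of scope.

The didactic `rsa_homomorphism_demo()` exists because unpadded RSA,
$E(x) = x^e \bmod m$, is the textbook *multiplicative* partial
homomorphism ($E(x_1)E(x_2) = E(x_1 x_2)$): it illustrates why a
"partial" scheme supports one operation only, and it is flagged insecure
in both code and output.

## Secure collaboration

**Pooled GWAS via additive shares.** Each party computes its local
per-site, per-group integer counts; a count $v$ is split as
$v = s_1 + s_2 \bmod p$ with $s_1$ uniform, over the Mersenne prime
$p = 2^{61}-1$ (counts never exceed a few thousand, so the field has
enormous headroom; 61-bit elements cross R's numeric boundary as decimal
strings and are serialized as fixed 8-byte big-endian words). Parties
exchange one share of each local count plus the masked partial sums, so
the transcript consists of uniform field elements; only the pooled
per-site counts are reconstructed, at both parties symmetrically. The
disclosure boundary is deliberate: pooled counts are the "intermediate
results" this model permits, and hiding them too would require garbled
circuits (out of scope). In a two-party setting a party can of course
subtract its own contribution from a pooled count; that is inherent to
revealing pooled aggregates, not a protocol defect.

**Distances via PSI cardinality.** Each genome is a set of canonical
variant keys (below). The parties run a classic Diffie–Hellman private
set intersection cardinality: hash each key with SHA-256, map into the
quadratic-residue subgroup of the RFC 3526 2048-bit safe prime by
squaring, double-exponentiate with per-party secret exponents (256 bits,
comfortably above the 80-bit floor), shuffle before returning (mandatory
— otherwise positions leak which keys matched), and count equal
double-blinded elements. Both parties then finish
$|A| + |B| - 2|A \cap B|$ locally. The group is a fixed well-known safe
prime rather than freshly generated: generating a 2048-bit safe prime
takes minutes and adds nothing, since the group is public parameter
material. Revealed information: set sizes and the cardinality — exactly
the output.

## Variant keys and the edit-distance approximation

A genome in VCF is a set of differences from the reference. The
canonical key is `(chrom, pos, ref, alt, zygosity-class)` with VCF-native
1-based coordinates throughout. Zygosity-aware keys are the default: a
heterozygous and a homozygous-alternate call at the same site are
different genomic states, and a difference between them is a genomic
difference. A site-only mode exists for sensitivity analysis. Indel
representations are *not* left-aligned or trimmed; exactness against
datasets with inconsistent indel anchoring would require revisiting
this. Only records with FILTER `PASS` or `.` are kept; multi-allelic
records split into one key per alternate allele.

**Hamming distance** between two genomes is the size of the symmetric
difference of their key sets — positional string alignment is undefined
for indel-bearing genomes, so the keyed-set form is the defensible
definition, and it is what the secure protocol computes.

**Approximate edit distance.** Shared variants change both sequences
identically and cancel; each private variant costs about one edit. The
set difference is read *symmetrically* (a one-sided difference could not
approximate a symmetric distance). Two regimes break the one-key-one-edit
accounting: different alternate alleles at the same position (two keys,
one substitution — the approximation overshoots) and multi-base indels
(one key, several edits — it undershoots). The optional
`indel_length` weighting charges each differing key
$\max(|\mathrm{ref}|, |\mathrm{alt}|) - \mathrm{lcp}$ edits for the
second regime; whether the original benchmark weighted indels is not
knowable from the published material, so both modes are exposed and
cardinality (which coincides with Hamming) is the default.

Deviation is reported as a percentage of the **true** (DP) distance, one
decimal: an approximation of 28 against a truth of 27 is $1/27 = 3.7\%$.
This convention is pinned by a constructed worked example in the test
suite. The exact Levenshtein oracle is a two-row rolling DP in compiled
code; a banded variant was considered and rejected — correctness first,
and 5000×5000 DP costs milliseconds in C++.

## The synthetic benchmark generator

The generator produces every input the toolkit consumes, at the
emulated study conditions; its defaults are fixed, not tuning knobs.

**Genotypes.** 200 cases + 200 controls over 311 sites by default (a
610-site panel is the second canonical size; site count is exposed
because the source material is inconsistent about 610 vs 611, which we
do not resolve). Per-site population frequencies are uniform on
[0.05, 0.5] — the common-variant range where the allelic test is well
behaved. Controls are drawn by resampling haplotype pairs from a
simulated pool of 2×174 haplotypes, structurally mirroring controls
built from a fixed reference panel of 174 individuals; an i.i.d.
binomial mode provides a simpler null. Cases (real genomes in the
original setting) are simulated with an allele-frequency shift at chosen
sites parameterized by an allelic odds ratio — the simplest mechanism
that makes the association task non-trivial. The generator has no LD
structure, recombination or demography; passing tests therefore show
protocol correctness and statistical calibration under HWE-style
sampling, not robustness to realistic population structure.

Calibration note: the type-I-error check runs in i.i.d. mode. The
haplotype-pool mode draws controls from a finite pool, which induces
within-group correlation the chi-square does not model — it is a
realism feature, not a calibration null.

**Genome pairs.** Shared-core-plus-private-variants construction with
exact sizes and exact planted intersection; positions drawn from a site
universe of 10× the total size by default; 5% one-base indels. Pairs
round-trip through single-sample VCF.

**Segment pairs.** 20 pairs derived from ~5000-nt random references;
25–50 variants per side, 90% SNVs / 10% single-base indels, minimum
spacing 5. Spacing is enforced across the **union** of both sides'
positions: two real genomes' private variants essentially never hit the
same base of a 5-kb window, and the approximation targets exactly that
low-density regime (the published validation found 18/20 pairs exact).
Under this recipe the approximation is exact for every generated pair;
the regimes that break exactness are exercised separately by constructed
pairs (same-position different-alt collisions) and by the multi-base
indel weighting tests, rather than left to rare collisions of the
generator.

## Numerical and engineering choices

* All big-integer arithmetic (modular exponentiation, inversion,
  Miller–Rabin, SHA-256) lives in compiled code on top of OpenSSL's
  BIGNUM, with hex strings at the R boundary. Counts are small integers,
  so every statistic is computed identically — the same R code path —
  from plaintext and from decrypted/reconstructed counts, which is what
  makes "bit-identical" a meaningful contract.
* Every source of randomness (keys, encryption randomizers, shares, PSI
  secrets and shuffles, all simulations) flows through R's RNG, so a
  single seed reproduces an entire protocol run byte for byte,
  including channel byte counts. Production keys should be generated
  with fresh OS entropy (i.e. without seeding).
* The channel is an in-process, append-only, byte-counted transcript;
  communication cost is the serialized message size per direction.
  Timings are reported in metrics but never asserted in tests
  (hardware-dependent); storage is a serialized-object-size proxy, which
  is deterministic and portable, not RSS.
* Degenerate inputs: all-missing sites produce zero counts and `NA`
  statistics identically through every route; zero marginals are `NA`
  with a warning; a PSI hash collision between distinct keys
  (probability ~$2^{-256}$) is detected and aborts rather than
  miscounting.

## Problem sizes used in the shipped checks

The test suite exercises: 50 HE-outsourced and 50 two-party GWAS
instances at 200+200 samples (site counts spanning small panels up to
the 311- and 610-site canonical sizes), all required to match the
plaintext pipeline exactly; PSI distances on 5K- and 100K-key pairs;
10,000-message Paillier identity checks at test key size plus a
1024-bit spot check; a 2000-site null calibration; and the 20-pair
segment validation. These sizes keep a full run in the minutes range on
one CPU while covering the emulated study conditions.

## Known limitations

* Semi-honest adversaries only; no malicious security, no network fault
  tolerance (the socket transport is simulated in-process).
* Pooled per-site counts are revealed to both GWAS parties by design;
  PSI reveals set sizes.
* No indel normalization; variant keys are representation-sensitive.
* The generator's realism limits (no LD, no demography, planted effects
  via frequency shift) mean statistical-power results here do not
  transfer quantitatively to real cohorts.
* Timing comparisons against published team benchmarks are explicitly
  not reproduced: they depend on private data subsets and hardware.
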