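---
title: "Vectorized secure variant annotation and aggregation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vectorized secure variant annotation and aggregation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectann)
```

## The problem

A researcher holds variant calls (or a genotype matrix) that must not be
revealed — variant loci and alleles re-identify individuals — yet wants two
routine computations performed by an untrusted server: *annotation* (which
consequence does each variant have on each overlapping transcript?) and
*aggregation* (what is the allele count at each position across many
samples, possibly pooled across databases holding data under different
keys?). The threat model is honest-but-curious: the server follows the
protocol but may inspect anything it stores. The annotation database itself
(gene models, impact of every possible mutation) is public; only the
researcher's variants and genotypes are sensitive.

The trick that makes both tasks cheap under SIMD-style homomorphic
encryption is to stop representing variants as sparse records and represent
them instead as dense binary vectors over a *public* coordinate system that
enumerates every possible point mutation on the regions of interest. The
server then never learns which entries are set: it always receives an
encrypted vector of fixed, public length.

## Target regions and the stitched coordinate system

Computation is restricted to extended coding regions: every CDS segment is
extended by `l_ext` bases on each side (default 10 bp, enough to cover the
splice donor/acceptor dinucleotides and the standard splice-region window),
so the consequential mutations — coding changes and splice disruptions —
are all representable. `build_transcript_targets()` emits one region per
CDS segment per transcript; `build_gene_targets()` deduplicates segments
within a gene on (start, end, frame), since copies identical in all three
cannot differ in annotation.

Regions are sorted by chromosome, start, element id (then end and frame as
tie-breaks so the layout is a total order) and *stitched*: vector
coordinate $\nu \in [1, l_T]$, with $l_T = \sum_i (e_i - s_i + 1)$, indexes
the concatenation of all regions. A genomic position covered by $k$ regions
appears $k$ times — deliberately, so each transcript's annotation of the
same base stays independent. Mapping $\nu$ to its region is a binary search
over cumulative lengths; mapping a genomic position back yields the *set*
of its vector coordinates. One convention needed fixing: with offsets
$\nu_{<k}$ defined as nucleotides covered *before* region $k$, the mapping
that makes $\nu = 1$ land on the first base of the first region is
$c(\nu) = s_k + (\nu - \nu_{<k} - 1)$, and the round-trip identity
(`vector_to_genomic()` then `genomic_to_vector()` contains the original
$\nu$) is the governing law the tests enforce.

## Packed impact values

For each allele of the point-mutation alphabet — the four SNV alternate
bases plus the 1-bp deletion state `d` and 1-bp insertion state `i` — the
server precomputes, at every target position, a packed 58-bit impact value:

* a 38-bit consequence bitmap over the frozen vocabulary of
  `impact_terms()` (the 20 coding-region terms in table order, completed to
  38 with the remaining standard consequence terms, alphabetically — the
  completion is documented as a package convention, since bitmaps are only
  interoperable if the index order is a public constant);
* an 18-bit neighborhood: the 6 bases flanking the position (3 each side,
  plus-strand, 3 bits per base A/C/G/T/N). For insertions the junction
  between $\nu$ and $\nu + 1$ is flanked, so the left triplet includes
  $\nu$ itself;
* a 2-bit coding frame: how many bases of the current codon lie 5' of the
  position (0 for non-coding positions; for insertions, 5' of the
  junction).

`pack_impact()` computes `(((bitmap << 18) + neighborhood) << 2) + frame`,
which tops out below $2^{58}$ and is stored in a 64-bit slot. Because R's
doubles are only exact to $2^{53}$, the package carries a small
Rcpp-backed integer-64 vector class (`as_i64()`); all slot arithmetic is
exact 64-bit integer arithmetic with an overflow guard at $2^{62}$ (also
keeping every bit pattern clear of IEEE NaN payloads).

## The consequence model

The built-in annotator assigns, per transcript: UTR/intron/upstream/
downstream classes positionally; splice donor and acceptor as the 2
intronic bases at each end of each intron; splice region as 1–3 exonic or
3–8 intronic bases from a junction; and codon-level terms by translating
the affected codon (synonymous, missense, stop gained/lost/retained, start
lost). Conventions worth stating:

* The CDS *includes* the stop codon: the last three coding bases in
  translation order are the stop, and the first three the start. GENCODE
  style separate `stop_codon` rows are merged into the CDS on load.
* Transcripts tagged as nonsense-mediated decay, or with
  start/stop-not-found tags, or whose CDS length is not a multiple of 3,
  are excluded on load — their annotations are not trustworthy input. The
  multiple-of-3 rule is this package's operationalization of "incomplete
  coding sequence"; annotation sources flag it inconsistently.
* `start_retained` is never emitted: a mutated start codon is a start loss
  even if an ATG is re-formed, because translation initiation depends on
  the surrounding context (Kozak-like motifs), which a retained codon does
  not preserve. `stop_retained_variant` *is* emitted — stop codons need no
  context.
* A 1-bp insertion is attributed to the position after which it occurs. An
  insertion is *coding* when the base 5' of the junction (in translation
  order) is coding and not the final coding base; this includes insertions
  at an exon's 3' junction, which extend the exon rather than disrupt the
  splice motif.

## Secure annotation and the 1-bp merge

The client encodes variants as binary loci vectors $\Lambda_a$ (`parse_vcf()`
→ `vectorize_loci()`), encrypts them, and the server multiplies slot-wise
with its plaintext packed annotation vector $I_a$. The product decrypts to
the packed impact exactly where a variant exists. SNVs translate directly:
non-zero slot → region → genomic position, bitmap → terms.

Deletions of arbitrary length are represented as runs of 1-bp deletion
states, and their annotation is *merged* at translation time: the number of
deleted coding bases (frameshift unless a multiple of 3), unions of
positional terms (splice/UTR/intron losses), start/stop losses from the
per-base flags, and the junction codon rebuilt from the stored
neighborhoods — the $f$ bases of the interrupted codon 5' of the deletion
joined with $3-f$ bases 3' of it — checked against TAA/TAG/TGA for a stop
gain, or a stop retention when the original stop was itself deleted. A new
codon only exists when $f > 0$ or the deleted coding count is not a
multiple of 3; otherwise whole codons were removed and no junction check
is made. Insertions translate analogously, reading the inserted sequence in
frame at the junction. Runs of non-zero slots cannot delimit *adjacent*
deletions, so translation consumes the client's own variant list for spans
and uses the run structure purely as a consistency check (a zero slot
inside a span, or a non-zero slot outside all spans, is an error).

Two limitation classes are inherent to the one-codon genomic junction
window and are *expected* to diverge from full-variant annotation: (i)
stop codons created downstream of the window by a frameshift, and (ii)
junction codons whose flanks cross a splice boundary, where the true
post-splicing context differs from the genomic neighborhood.
`junction_divergent()` flags the affected (variant, element) pairs from
geometry alone — deliberately a superset of actual disagreements — and the
test suite asserts exact agreement of the six HIGH-impact terms with the
direct annotator everywhere outside that class, and membership in the
class for every disagreement inside it.

## Aggregation and key switching

Genotype matrices are encoded per allele as $l_T \times n_G$ integer
matrices, as allele dosages \{0,1,2\} or existence flags \{0,1\} (the
2-level encoding used for beacon-style counts). Aggregation is a slot-wise
sum over samples, performed on ciphertexts (one per sample, chunked at the
slot bound). Counts stay raw integers; allele frequency is a presentation
division by $2 n_G$ (or $n_G$), so encrypted results remain exact.

The exact-span deletion statistic counts, per position, samples whose
deletion state is 1 on the whole window $[\nu, \nu + l_\delta]$ and 0 at
both flanks. The window covers $l_\delta + 1$ positions — the source
formulation's index convention, kept verbatim; `aggregate_deletion_span()`
is the off-by-one-free wrapper taking the deleted-base count. Flanks
outside the vector or outside the containing region count as 0, windows
crossing a region boundary are invalid, and deletions not fully contained
in a region are excluded at encoding time, so only engulfed deletions are
aggregated. The encrypted evaluation multiplies shifted copies of the
sample's cipher ($l_\delta + 3$ multiplicative depth) with plaintext
region-geometry masks; whether a deployment evaluates this under
encryption or after decryption is left open by the protocol, so both paths
exist and are tested against each other and an independent run-length
oracle.

Pooling across $M$ databases uses proxy re-encryption: a trusted key
manager (the role a data custodian like a national archive would play)
generates directional switching keys from each owner's key to the
researcher's key; the server re-encrypts each source's aggregate and sums.
The mock backend enforces every key contract (tagged ciphertexts, refusal
on mismatch, server operations that never accept secret material) so the
protocol's trust boundaries are testable without cryptography; a real
lattice backend can be substituted behind the same seven-operation surface
(`keygen`/`gen_switch_key`/`he_encrypt`/`he_decrypt`/`he_add`/`he_mul`(`_plain`)/
`key_switch`, plus `he_shift`). The mock declares an exact-value capacity
of $2^{62}$ and `he_encrypt()` enforces it, which is the headroom contract
callers must satisfy (packed values $< 2^{58}$, counts $\le 2 n_G$).

## The synthetic-data generator

`simulate_reference()` builds the study conditions used throughout the
tests: a 1 Mb chromosome with 50 protein-coding genes on both strands, 2–5
CDS exons per transcript, valid ORFs by construction (ATG start, stop at
the end, no internal in-frame stop, CDS length divisible by 3), second
transcripts that either share the CDS exactly with different UTR extents or
skip a codon-aligned internal exon, NMD-tagged transcripts for the filter,
and occasional genes nested inside another gene's intron (overlapping gene
pairs). `simulate_variants()` mutates each unique covered position
independently with probability 0.25 per variant type, draws the alternate
base uniformly from the three non-reference bases and indel lengths
uniformly from [1, 10] with random inserted sequence — the simulation
protocol the method was characterized under. `simulate_genotypes()` draws
per-site allele frequencies from a Beta(0.5, 5) spectrum (a rare-variant-
heavy shape typical of population sequencing) and Hardy–Weinberg diploid
genotypes. All generators are deterministic under the configured seed and
leave the caller's RNG state untouched.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: realistic splice-site motifs (classification is
positional, so none are needed), mutation-rate heterogeneity, linkage
disequilibrium and population structure, multi-allelic sites and
non-normalized indel representations (left-alignment is assumed done
upstream), and annotation-source quirks such as CDS records that exclude
the stop codon without separate stop rows.

## Numerical and design choices

* Problem sizes: the default conditions give $l_T$ in the tens of
  thousands, annotation vectors build in a couple of seconds, and the full
  end-to-end comparisons (≈13,000 variants, ≈20,000 per-transcript records)
  run in about a minute — chosen as desk-scale conditions that still
  exercise every code path, including overlapping transcripts and both
  strands.
* The calibration check for the 25% mutation rate uses the binomial with
  $n$ = the number of *unique* covered genomic positions, which is what the
  generator draws over; $l_T$ counts positions with multiplicity and is not
  the binomial's $n$ on fixtures with overlapping transcripts.
* Deletion translation evaluates, per element, the part of a deletion
  visible in that element's target regions (flagged `engulfed = FALSE`
  when truncated); the direct annotator uses the same visibility so the
  two paths are comparable. Length-specific deletion vectors (one
  annotation vector per deletion length) are the exact-by-construction
  alternative the coordinate system supports; the merge path is the
  default because it needs a single vector.
* In gene mode a variant may overlap elements with conflicting frames;
  records are emitted per element by default, with `collapse_records()`
  as the explicit worst-case summarizer — neither behavior is claimed to
  be canonical.
* Key ids are session-unique counters, not random, so simulation seeds are
  not consumed by key generation.
* The CLI (`inst/cli/vectann.R`) is a thin wrapper over these functions;
  stage manifests carry a target-set hash so a vector can never be
  annotated against the wrong coordinate system. The client/server
  exchange runs in one process there; the trust boundary is the package
  API itself (no server-side function accepts a secret key).

## Known limitations

Downstream stop codons beyond the one-codon junction window and stop gains
across spliced exon junctions (the two divergence classes above); no
aggregation of inserted-sequence identity (insertion positions aggregate
like SNVs); no structural variants, phasing, or multi-sample VCF merging;
splice classification is positional, not motif-aware; and the real-HE
adapter is a contract, not an implementation — the mock is exact but
provides no confidentiality.
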