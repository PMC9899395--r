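---
title: "Designing multi-enzyme GBS protocols with gbs3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-enzyme GBS protocols with gbs3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbs3d)
```

## The problem

Genotyping-by-sequencing reads only the genome next to restriction cut
sites, so three choices determine everything about a protocol: which
enzymes cut, which fragments enter the library, and how many reads each
sample receives. `gbs3d` models each choice explicitly so a design can be
evaluated on a reference genome before any wet-lab work.

The model of the sequenced library is:

1. **Digestion.** Every match of an enzyme's palindromic IUPAC recognition
   site on the top strand is cleaved at a fixed offset within the site
   (the `*` of the conventional notation, e.g. PstI `CTGCA*G`). Matches may
   overlap; windows containing `N` never match.
2. **Adapter compatibility.** The 5' adapter ligates only to the common
   overhang of the rare cutters (default PstI and NsiI); the 3' adapter
   only to the frequent cutter's overhang (default MspI). A fragment is
   amplifiable iff its two ends carry one of each — rare–rare,
   frequent–frequent and terminus-ended fragments are lost.
3. **Size selection.** Only inserts inside a length window (default
   50–350 bp) are retained.
4. **Sequencing.** Reads land on the selected fragments; with `N` reads
   over `F` fragments the per-fragment depth is modelled as Poisson with
   mean `lambda = N / F`, so the expected missing-data (dropout) fraction
   is `exp(-lambda)` and `P(depth < d)` is the Poisson CDF at `d - 1`.

## Enzyme arithmetic

On i.i.d. uniform DNA, a site of length `L` with `k` concrete expansions
matches each position with probability `k / 4^L`, and successive sites are
`4^L / k` bp apart in expectation. This closed form reproduces the figures
used to rank candidate cutters: 4096 bp for the 6-bp cutters PstI and NsiI,
256 bp for MspI, and 512 bp for ApeKI (`GCWGC`, one two-fold ambiguity, so
effectively a 4.5-bp cutter):

```{r}
expected_spacing(c("CTGCAG", "ATGCAT", "CCGG", "GCWGC"))
gc_content(c("CTGCAG", "ATGCAT", "CCGG", "GCWGC"))
```

GC content is the per-position probability of G/C averaged over IUPAC
expansions, truncated to an integer percent (so `CTGCAG` is reported as the
conventional 66%). The exact value is available as `gc_fraction()`. Real
genomes are not i.i.d.: regional GC and methylation skew realized spacings,
which is why `evaluate_combinations()` exists — the closed form ranks
candidates, the genome scan decides.

Note one registry subtlety: BfaI's site `CTAG` has 50% GC by computation,
even though it is sometimes grouped with the 100%-GC frequent cutters; the
registry stores real sites and the arithmetic reports the truth.

## Methylation model

Enzyme sensitivity to cytosine methylation is a three-level class on the
enzyme (`none`, `partial`, `full`); its quantitative effect is a digestion
parameter. Given a methylation track (0-based cytosine positions; a
position on a `G` is read as the bottom-strand cytosine):

- `full`: a matched site containing **any** methylated cytosine in the
  duplex window is never cut. PstI is blocked by CpG/CHG methylation within
  its site and no finer model is warranted, so any-cytosine blocking is the
  conservative choice.
- `partial`: such sites are suppressed independently with
  `partial_block_prob` (default 0.5, seeded). The literature calls ApeKI
  "partially sensitive" without quantifying; 0.5 is a neutral default and
  the parameter is exposed.
- `none`: never suppressed.

Without a methylation track no suppression occurs for any class. We
deliberately did not implement blanket random suppression of
partial-sensitivity enzymes in the absence of a track: that would delete
half of all ApeKI sites on a fully unmethylated genome and make raw
in-silico cut counts irreproducible. Both the raw scan (no track) and the
methylation-aware scan are therefore available, and combination reports can
be produced under either.

## Coordinates and numerical conventions

- All genomic intervals are 0-based half-open; a cut at coordinate `c`
  falls between bases `c - 1` and `c`. VCF positions (1-based) are
  converted only at the VCF boundary.
- Only the top strand is scanned, and non-palindromic sites are rejected
  rather than half-scanned, so the scan is complete by construction.
- If two enzymes cut at the same coordinate the first-listed enzyme labels
  the boundary and a warning is raised — deterministic and observable.
- `percent_reduction()` rounds halves away from zero, matching how
  headline cost-reduction percentages are conventionally reported.
- Size selection acts on insert length plus a configurable
  `adapter_extension` (default 0): published windows refer to the
  adapter-ligated molecule, but adapter lengths vary by platform, so the
  correction is a documented knob rather than a hidden constant.
- Mirrored genomes: digesting the reverse complement preserves interior
  fragment lengths exactly; the two terminal fragments shift by
  `|L - 2 * offset|` for off-center cutters. The tests assert this exact
  form.

## Read budgets

`gbs_budget()` treats reads as one observation per fragment copy
(single-end sequencing of short inserts), so depth is per fragment, not per
base. The Poisson approximation to the multinomial allocation is exact in
the limit of many fragments; `simulate_reads()` provides the exact
multinomial draw, plus an optional log-normal capture-bias dispersion
(sdlog), since real libraries never sample fragments uniformly — bias
raises dropout at fixed effort. The inverse mode
(`reads_for_depth(F, lambda)`) returns the minimal read count reaching a
target depth.

The per-fragment `lambda` is *not* directly comparable to a variant
caller's "mean depth of coverage" computed over variant positions only;
it is the design-time quantity that controls dropout.

## Variant filtering

`filter_variants()` implements the standard post-calling hard filters with
a recorded first-failing-reason per record, in fixed order: `low_qual`
(QUAL below 10), `low_mq` (INFO/MQ below 30, missing MQ fails
conservatively), `scaffold`, `indel`, `multiallelic`, `missing`
(missing-call rate must be strictly below 0.8 to retain), `het` (site
heterozygosity strictly below 0.1). Two readings of the usual "QUAL < 10
and MQ < 30" phrasing exist; the default removes a record when **either**
condition holds (two removal criteria), and `qual_mq_rule = "both"` gives
the conjunctive reading. Heterozygosity here is per site among non-missing
calls — it is a site-retention filter; per-sample heterozygosity is
reported separately by `diversity_stats()`.

## Marker distribution diagnostics

Densities are totals over total span (SNP/Mb over genome length, SNP/cM
over map length). A gap is a distance between *consecutive* markers on one
chromosome strictly greater than the threshold (defaults 5/10 Mb physical,
10/20 cM genetic); flanks to chromosome ends are excluded by default and
available via `include_ends = TRUE`, since published gap counts are
inter-marker by construction and end behaviour deserves an explicit
switch. Genetic positions come from the nearest consensus-map anchor by
physical distance, ties to the smaller bp anchor; markers on chromosomes
absent from the map are flagged unplaced rather than dropped silently.

Nucleotide diversity uses the unbiased per-site estimator
`pi = (1 - sum p_k^2) * n / (n - 1)` over non-missing alleles (for a
biallelic site, `2p(1-p) n/(n-1)`). Published "pi per bp" values from other
toolchains normalize differently, so values are structurally comparable
but not guaranteed numerically identical. The IBS distance is
`1 - mean(shared alleles) / 2` over sites where both samples are called
(shared alleles = multiset intersection of the two diploid genotypes);
IBS variants differ in heterozygote handling across tools, so the formula
is stated and tested rather than matched to any one program.

## Synthetic data: what it does and does not emulate

The generators produce i.i.d.-composition genomes (optionally with a
linear GC gradient), Bernoulli CpG methylation, evenly anchored monotone
genetic maps with truncated jitter (maps are monotone by construction, so
jitter is capped below half the anchor spacing), and VCFs whose QUAL, MQ,
missingness, heterozygosity, allele-frequency, indel and multiallelic
structure follow stated distributions. VCF truth flags are generated
*with* the data (constructive testing), so filter tests are oracle-exact
rather than re-derivations.

Defaults follow the study conditions this toolkit targets: 16 samples per
library, the PstI+NsiI+MspI enzyme set with a 50–350 bp window, read
budgets in the 50K–300K range, and a genome-wide average recombination
rate of 2.5 cM/Mb typical of a compact plant genome.

What synthetic data deliberately lacks: linkage disequilibrium, demographic
structure, compositional isochores, repeat content, read errors and PCR
duplicates. Consequently, passing tests demonstrate correctness of the
*computations* (scanning, selection, budgets, filters, distances), not
that an i.i.d. genome predicts a real genome's coverage — on real genomes
the same functions should be run on the actual reference FASTA and
methylation track.

## Problem sizes

The test suite verifies spacing convergence on a 10 Mb genome (observed
vs expected spacing within 5%), scanner equivalence against a naive
IUPAC-expansion search on one hundred 50 kb genomes, Poisson dropout at
10,000 fragments for `lambda` in {1, 5, 10} (within 3 Monte-Carlo
standard errors), filter truth on a 1,000-site VCF, and brute-force
agreement for gaps, anchors and distances on seeded random fixtures.
These sizes were chosen so the full suite runs in a few minutes on a
laptop while leaving the statistical checks well-powered.

## Known limitations

- Only palindromic Type IIP enzymes are supported; Type IIS
  (outside-cutting) enzymes and nicking enzymes are out of scope.
- Digestion is complete (no partial-digestion kinetics); star activity and
  buffer effects are not modelled.
- The read model has no PCR-duplicate or GC-amplification bias beyond the
  log-normal dispersion knob, and no base errors.
- `subsample_fastq()` guarantees uniformity and per-seed determinism, not
  bit-identical agreement with any particular external sampler.
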