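---
title: "Pathway phenotype sequencing: models, parameters and design choices"
author: "phenoseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway phenotype sequencing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters
and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical conventions
adopted where the design was genuinely open.

## The experimental design being modelled

A parent strain is chemically mutagenized (NTG or similar) in many
*separate* experiments; one colony per experiment is screened for the
phenotype, so every selected strain is an independent draw from the
space of mutational causes.  Strains are pooled a few per tagged
sequencing library.  Three consequences shape the analysis:

* each strain carries on the order of 100 point mutations, nearly all
  of them passengers;
* a variant cannot be assigned to a strain within a pool, only to the
  pool, with an allele-frequency estimate near (carrier count)/(pool
  size);
* causal genes reveal themselves only through *recurrence* across
  strains, so the test statistic is a count of independent hits
  against a neutral mutagenesis model.

## Variant filtering

Four filters are applied in a fixed order, and each removed call is
attributed to the first filter that rejects it (so the exclusion
report partitions the removals):

1. `qual_min` (default 90, strictly greater-than): the caller's
   phred-scaled confidence.
2. `strand_bias_p_min` (default `1e-4`): calls whose support comes
   almost entirely from one read direction are sequencing artifacts.
   The cutoff is an operating point, not a published constant; it is
   exposed as configuration, logged in the run manifest, and calls
   lacking the annotation pass.
3. `af_max` (default 0.5): an independent mutation should be carried
   by one of the `pool_size = 3` strains in a pool, i.e. AF near
   1/3.  Estimates above 1/2 indicate either a shared (parental)
   variant or a miscalled region.  The comparison keeps AF = 0.5.
4. `max_pools` (default 1): a site present in more than `max_pools`
   distinct pools cannot be an independent mutation of a single
   strain; in practice such sites appear in *all* pools and are
   parental differences from the reference assembly.

Filtering is idempotent and order-insensitive in the surviving set;
both properties are asserted in the test suite.

## Effect annotation

CDS features are taken from a GenBank reference (a minimal flat-file
parser handles `complement()`/`join()` locations; locus tags and gene
symbols both resolve group membership, case-insensitively).
Substitutions are classified by substituting the mutated base into
the affected codon of the strand-corrected coding sequence and
comparing amino acids under the bacterial code (NCBI table 11,
configurable).  Conventions, chosen for simplicity and symmetry:

* start codons get no special handling: a mutation there is
  classified by ordinary translation;
* mutations creating a stop codon are nonsynonymous;
* a variant inside several overlapping CDSs contributes one hit to
  each (no precedence rule);
* CDSs of non-triplet length (pseudogene-like entries) are flagged,
  excluded from effect calling, and logged.

The classifier is validated against a brute-force oracle that
re-translates the whole mutated gene for every possible point
mutation, on both strands.

## The Poisson target model

Under neutral mutagenesis, the number of mutations falling in a
region is approximately Poisson with mean proportional to the
region's *mutational cross-section*.  NTG hits G:C pairs far more
often than A:T pairs, so the cross-section separates the two site
classes:

$$\lambda_u = n^{GC}_u\,\rho_{GC} + n^{AT}_u\,\rho_{AT},$$

where $n^{GC}_u, n^{AT}_u$ count G/C and A/T positions in the unit's
genomic span and $\rho$ are genome-wide per-site mutation densities
estimated from the filtered data themselves.  A gene group's
cross-section is the sum over member genes.  The score of a unit with
$m$ observed nonsynonymous mutations is the upper tail
$P(X \ge m),\ X \sim \mathrm{Poisson}(\lambda_u)$, Bonferroni-multiplied
by the number of groups in the database (not merely the number hit).

**Which mutations feed the densities?**  Two readings are tenable:
estimate $\rho$ from *all* observed mutations, or from the
nonsynonymous ones only (the class actually scored).  The package
defaults to `mode = "all"` and this is a deliberate calibration
choice: nonsynonymous mutations exist only inside coding sequence
(~88% of a typical bacterial genome), so dividing their count by
*genome-wide* site totals under-estimates every unit's $\lambda$ by
roughly the non-coding fraction, which at group-scale counts turns
into a materially anti-conservative score (in simulation, ~9% of null
groups reach $p < 0.05$).  With all mutations in the numerator the
expected count over-covers the nonsynonymous-only observation and the
null p-values are super-uniform — the conservative direction.  The
`"nonsynonymous"` mode is retained for comparison and recorded in
output headers either way.

The cross-section uses the gene's genomic-span composition, not a
codon-position-aware count of nonsynonymous opportunities; that finer
model is deliberately out of scope, matching the published recipe.

Ranking ties (identical raw p-values) break by descending observed
count and then unit id, so output is deterministic.

## Positive selection, enrichment, causal counts

**Selection.**  Causal mutations must change the protein, so a causal
group's nonsynonymous:synonymous ratio should exceed the genome-wide
ratio (which for an unscreened mutagenesis is neutral, Ka/Ks ≈ 1).
The test is the one-tailed ("greater") Fisher exact test of
`[[ns_in, syn_in], [ns_tot − ns_in, syn_tot − syn_in]]`, applied
cumulatively down the ranked list.  No multiple-testing correction is
applied to the cumulative test: it is one planned comparison.  Group
databases often contain nested entries (a complex and its
super-complex); the default pooling is the *union of genes*, counting
each gene's mutations once however many listed groups contain them.
The alternative per-group summation is implemented (`mode = "sum"`)
because published cumulative tallies of this kind are not always
reconstructible under the union reading; neither mode is claimed to
be "the" historical bookkeeping.  The companion `ka_ks_like` value is
the count-ratio normalised by the genome ratio, reported as `Inf`
when the set has no synonymous mutations (no site-opportunity
normalisation is attempted).

**Enrichment.**  Whether the top `K` gene-level hits cluster inside a
group is scored by the hypergeometric upper tail, with the candidate
universe defaulting to genes carrying at least one nonsynonymous
mutation.  Only groups intersecting the top list are tested, and the
Bonferroni factor is the number tested.  `K` defaults to 50 and is a
free parameter.

**Causal counts.**  Assuming causal mutations are all nonsynonymous
and passengers follow the background mixture, a unit's observed
nonsynonymous fraction is $x = c + (1 - c) f_0$, giving
$\hat c = (x - f_0)/(1 - f_0)$ and an estimated causal count
$\hat c N$.  Conventions: $f_0$ defaults to the filtered dataset's
own nonsynonymous fraction (overridable); counts are rounded to the
nearest integer half-away-from-zero (published tables report
integers); negative $\hat c$ is clamped to zero with the raw value
retained in a diagnostic column.  The estimator is unbiased in $x$,
hence in the *unclamped* $\hat c$; recovery tests therefore average
`c_raw`, and the clamped `c` is the reporting value.

## The Wright–Fisher simulator

`simulate_wf()` motivates the non-competitive screening design: it
grows `n_strains = 26` founders (one cell each) to a carrying
capacity (default $10^6$), then resamples the population
multinomially with probabilities proportional to count × fitness for
`n_generations = 30` generations, over `n_replicates = 1000`
replicate populations, tracking the distinct-strain count and the
Shannon entropy (base 2, reported in bits) of the composition.

Two pieces of the published setting are unrecoverable and are treated
as explicit stand-ins: the fitness spectrum of a random mutant pool
(default: lognormal relative fitnesses, `sdlog = 0.05`, drawn per
replicate) and the growth rule.  Growth defaults to deterministic
doubling until capacity — the simplest reading of exponential growth
to a ceiling — under which no diversity is lost before capacity;
`resample_growth = TRUE` applies Wright–Fisher sampling at the
growing population size instead, which reproduces the rapid
early-generation strain loss (half the founders within ~7
generations) seen when a handful of founder cells drift.  The
headline qualitative claims — diversity decreases monotonically in
the mean, and any positive-variance fitness configuration loses
diversity at least as fast as the neutral one — hold under either
rule and are asserted over paired 1000-replicate runs.

## The synthetic experiment generator

`synth_config()` defaults *are* the modelled study conditions: 24
strains, Poisson(100) mutations each, 95% on GC sites (90%
transitions), pooled 3 × 8; a 500-CDS genome (CDS lengths uniform
750–1050 bp, Poisson(120) intergenic gaps, GC 0.5 — i.e. ~88% coding,
as in *E. coli*); 536 groups with sizes 2–8 skewed small; causal
structure implanted as one forced nonsynonymous mutation per strain
in a designated 2-gene group; pooled allele frequencies
carrier/3 + N(0, 0.03) jitter.  QUAL, strand-bias and parental
artifacts can be injected in known numbers to exercise each filter,
and the generating truth (per-strain mutation lists, per-gene
tallies, implanted identities) is returned alongside the calls.

What it does **not** emulate — and therefore what passing tests do
not establish about real data: sequencing reads and alignment error
(no read-level simulation; QUAL and strand-bias values are drawn,
not derived), real codon usage and ORF structure (gene sequences are
random, so internal stops occur — harmless to the codon-level
classifier but not biological), operonic/functional correlation of
group membership (groups are random gene sets), mutational
hotspots beyond the GC/AT dichotomy, and copy-number or indel
variation (the design observes substitutions only).  Two small
artefacts of the scale are worth knowing: with a 0.5 Mb genome,
independent strains occasionally draw the same site (birthday
collisions), so a handful of true mutations can legitimately fall to
the allele-frequency or multi-pool filters; the bookkeeping tests use
configurations/seeds where this does not occur, and the
power/calibration tests simply absorb it.

## Validation problem sizes

The acceptance-level checks run at the full modelled design: 100
generator replicates for causal-group recovery (the implanted group
must rank first with corrected $p < 0.05$ in ≥95%), 200 null genomes
× 536 groups for calibration, 1000 replicates per causal-fraction
level for estimator recovery, and paired 1000-replicate
Wright–Fisher runs.  Unit tests use a compact 60-gene configuration
of the same generator.

## Known limitations

* The Poisson model ignores overdispersion from strain-to-strain
  mutation-count variation; with ~24 strains this is minor, and the
  `"all"`-mode density choice keeps the net calibration conservative.
* Cross-sections are span-based, so a gene unusually rich in
  synonymous opportunity is slightly over-expected.
* The causal-count estimator is a point estimate with no interval;
  at small $N$ its granularity is coarse.
* Promoter/non-coding signal is not modelled: the scoring operates on
  CDS hits, though the group-scoring machinery accepts any unit with
  a site composition and a count.
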