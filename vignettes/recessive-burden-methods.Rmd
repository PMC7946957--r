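---
title: "Methods: recessive inheritance and gene-burden analysis"
author: "BiallelicBurden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive inheritance and gene-burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiallelicBurden)
```

## The problem

A gene can contribute to disease recessively even when its common risk
alleles were discovered under additive models: an individual is at high risk
when *both* copies of the gene are disrupted, either by a homozygous variant
or by two different deleterious variants inherited on opposite haplotypes (a
compound heterozygote, "trans"). Two variants on the *same* haplotype
("cis") leave one working copy and do not constitute biallelic loss.
Distinguishing the two from unphased short-read genotypes is the central
difficulty, and getting it wrong contaminates every downstream risk
estimate.

`BiallelicBurden` implements this analysis end to end for a single gene
(the motivating case is NOD2, the bacterial muramyl-dipeptide sensor whose
biallelic disruption drives a subset of early-onset Crohn's disease):
variant classification and frequency filtering, genotype QC, cis/trans
phasing from pedigrees and from population haplotype frequencies,
per-sample diplotype calling, contingency-table and penalized-regression
association statistics, electronic-health-record (EHR) case definitions,
and a phenome-wide scan. Because the genotype and health-record data such
studies use are protected, the package also ships a synthetic cohort
generator with the same statistical structure, so the full pipeline is
exercised by reproducible tests.

## Variant classification and frequency filters

Variants arrive annotated (the package consumes snpEff/dbNSFP-style
annotations; it never computes them):

* **pLoF** (predicted loss of function): stop gain, start loss, stop loss,
  canonical splice donor/acceptor disruption, or frameshift — a pure
  function of the consequence term.
* **pdNS** (predicted deleterious missense): a missense variant called
  deleterious by all five of SIFT, LRT, MutationTaster, PolyPhen2-HumDiv
  and PolyPhen2-HumVar. The conjunction is the default because the
  five-algorithm definition reads as one; `classifyPdns(rule = "k_of_five")`
  relaxes it. A missing vote counts as "not deleterious" — the conservative
  choice for a class that gates burden membership.

Frequency filters use a minor-allele-frequency (MAF) with a documented
precedence: an external reference-database frequency when present,
otherwise the analysis-cohort frequency computed over pedigree founders
(so transmitted alleles are not double-counted). "Rare" is strict
(`MAF < 0.02`); "low-frequency" is inclusive (`MAF <= 0.05`); both the
ceiling and the comparison are configurable because published usage mixes
the two conventions at the 5% boundary. The burden class set is either
`plof_only` or `plof_plus_pdns`.

## Genotype QC

Low coverage with skewed allelic balance makes heterozygous sites miscall
as homozygous — exactly the error that fabricates recessive genotypes.
`qcGenotypes()` demotes homozygous-alt calls with depth `< 10` or
alt-allele balance `< 0.85`; the default policy sets them missing
(`demote_to_het` is available). The thresholds are this package's declared
defaults, not published values: orthogonal confirmation (read inspection,
Sanger) is out of scope, and the QC rule is its in-silico stand-in.

## Phasing candidate compound heterozygotes

For a sample heterozygous at two qualifying variants, evidence is combined
in a fixed priority order:

1. **Pedigree** (`phaseByPedigree()`): TRANS when each variant is carried by
   exactly one parent and the parents differ; CIS when one parent carries
   both and the other neither; otherwise UNRESOLVED. Mendelian-inconsistent
   configurations are flagged and never forced to a verdict. Segregation
   evidence overrides everything else.
2. **Population** (`emHaplotypeFreqs()` + `phaseByPopulation()`): two-locus
   haplotype frequencies (pAB, pAb, paB, pab) are estimated from unrelated
   samples (founders, when a pedigree exists) by EM over the
   double-heterozygote ambiguity — the only ambiguous configuration; a
   homozygous locus forces phase analytically. The trans posterior for a
   double het is `pAb*paB / (pAb*paB + pAB*pab)`; verdicts use a 0.95
   posterior threshold (a package choice — no published numeric criterion
   exists for this step). The EM converges when the largest frequency
   change drops below 1e-10 (cap 1000 iterations, non-convergence is an
   error), and the observed-data log-likelihood is asserted non-decreasing
   at every step. A long-range statistical phaser is deliberately not
   re-implemented; for a two-locus decision the EM is the exact
   maximum-likelihood counterpart.
3. **Blacklist** (`applyCisBlacklist()`): pairs known to ride one haplotype
   (defaults: p.L1007fs+p.M863V and p.S431L+p.V793M) are excluded from
   compound-het candidacy outright; the sample remains a carrier of that
   haplotype.

`callDiplotypes()` folds the evidence into one category per sample — `REF`,
`CARRIER`, `HOM`, `CHET_CONFIRMED`, `CHET_PUTATIVE` (two or more hets, no
pair decidable: typically singletons), `CIS_EXCLUDED` — and the 0/1/2
genotype code used by the burden models: 0 for REF, 1 for CARRIER and
CIS_EXCLUDED, 2 for HOM and compound hets. Putative compound hets count as
2 by default (`includePutative = FALSE` demotes them to 1), matching the
reporting convention of including unphasable singletons among biallelic
carriers. With three or more hets the reported pair is the best-evidence
one, ties broken by ascending position.

## Association statistics

`genotypeCounts()` tables are analysed under every genetic model:

* **additive** — allele-level 2x2 (`het + 2*rec` alt alleles vs the rest);
* **genotypic** — het vs ref and rec vs ref, separately;
* **recessive** — rec vs everyone else;
* **carrier** — any-alt vs ref.

The point estimate is the unconditional cross-product odds ratio and the
interval is Woolf's (log-normal, `SE = sqrt(sum of reciprocal cells)`) —
the unique convention consistent with the published reference grid at two
decimals (those printed values are *truncations*, so equality tests use a
±0.01 absolute tolerance). Two p-values are reported side by side:
`p_score`, the Pearson chi-square score test without continuity correction,
and `p_fisher`, the exact two-sided Fisher summation. The reference grid's
printed p-values are reproduced exactly by the score test (despite being
labelled exact-test results at the source); the genotypic het/hom rows with
homozygous carriers match no standard 2x2 test we tried (Pearson with and
without Yates, likelihood ratio, Wald, one- and two-sided exact, against
ref-only and rest denominators) and are therefore documented here rather
than asserted. A zero cell flags the estimate undefined — reported `NA`
with a Haldane (+0.5) value alongside, never silently substituted.

**Firth burden regression** (`firthLogistic()`, `burdenTest()`): case
status is regressed on the gene-level genotype code (additive: 0/1/2;
recessive: indicator of 2) by maximizing the Jeffreys-penalized
log-likelihood `l(beta) + 0.5*log det I(beta)` with Newton iteration on the
modified score, step-halving so the penalized likelihood never decreases,
and convergence at score `< 1e-8` or step `< 1e-10` (cap 50). Estimates
stay finite under separation and equal the Haldane-corrected odds ratio in
the saturated 2x2 case — an identity the test suite uses as a closed-form
oracle, alongside a brute-force penalized-likelihood grid search.
Confidence intervals and p-values are Wald-type on the penalized estimate.
No covariates are used anywhere, matching the reference analysis; an
unrelated-subset filter is available but relatedness is otherwise ignored
in association.

One disclosed discrepancy: the published recessive-model burden odds ratios
(20.74 for pLoF-only, 13.15 with deleterious missense) are *not* the
penalized-likelihood optimum of the published genotype-code counts — no
standard estimator (crude cross-product 21.29/13.83, Firth 22.00/14.06,
conditional MLE 21.28/13.83) lands on them, while the published intervals
are exactly Wald intervals with the crude Woolf standard error around those
points. Back-solving suggests the original regression used slightly
different case totals or covariates. This package reports the optimum of
the data it is given; the additive burden odds ratios (2.69, 2.38) do
reproduce within 1%. Similarly, the published composite additive odds
ratio (1.64) is not reproducible by allele counting from the published
composite counts (cross-product 1.75); the test suite asserts the
documented discrepancy rather than the printed value.

## EHR operations

A subject is a **case** when a problem-list entry matches the code
prefixes, or matching encounter diagnoses occur on at least two distinct
calendar days (ICD-9 555*/556*, ICD-10 K50*/K51* by default; both systems
match only their own prefixes — no cross-walk). Onset is the age at the
earliest matching code in 365.25-day years, with pediatric (<18) and
early-onset (<30) flags; onset ages of recessive versus other cases are
compared by an unpaired pooled-variance t test (Welch optional). Subjects
with both Crohn's-type and colitis-type codes are flagged, never resolved —
adjudication is a chart-review task. `diagnosisLeadTime()` reports how a
comorbidity (default: anemia codes) precedes the first index diagnosis.
The **PheWAS** groups codes at a 3-character prefix (configurable), applies
the same two-encounter rule per group, tests each against the recessive
indicator by Fisher's exact test, and corrects across groups (Bonferroni
default, Benjamini-Hochberg available). The per-group test and the
correction rule are package choices; nothing published pins them down.

## The synthetic cohort generator

`simCohortConfig()` defaults *are* the study conditions the package is
tested under, chosen once:

* **Families**: 492 trios and 691 singleton probands (quartets supported,
  default 0).
* **Variant panel**: the three "common" low-frequency risk alleles at their
  clinical-cohort frequencies (p.R702W 0.050, p.G908R 0.017, p.L1007fs
  0.029), rarer deleterious alleles, the two cis pairs above, plus a
  synonymous and a 4-of-5-votes missense decoy for the classifier.
* **Haplotype model**: single-origin — a haplotype carries at most one
  panel allele, except designated cis groups carried jointly; marginal
  frequencies and per-variant Hardy-Weinberg proportions are exact. This
  repulsion structure is what independent mutational origin without
  intragenic recombination produces, it is what makes a double heterozygote
  a true trans compound het, and it keeps the putative-compound-het class
  honest. (Fully independent placement would make half of all chance double
  hets cis, poisoning the recessive class with null-risk samples and making
  odds-multiplier recovery fail by construction.)
* **Penetrance**: multiplicative on the odds scale — baseline
  `kappa0 = 0.019` (an IBD-like prevalence in a clinical population), odds
  multipliers `psiHet = 1.5` for carriers and `psiRec = 10` for recessive
  genotypes — so the simulated multiplier equals the odds ratio the
  association module estimates asymptotically, making recovery tests
  well-posed.
* **Diagnosis streams**: affected subjects get at least two encounter
  diagnoses on distinct days (so the case definition recognises them),
  mean onset 51.5 y with recessive carriers 8 y earlier, an ICD-9/ICD-10
  mix, optional problem-list entries and subtype-conflict codes, anemia in
  75% of affected (58% of those concurrent-or-prior with a mean 2.26-y
  prior lead), and background non-IBD codes for everyone.
* **Noise channels**: a true het becomes a low-depth, balance-skewed hom
  call with probability 0.01, and calls are flagged low-depth with
  probability 0.02 — only the observed matrix is corrupted; the truth table
  is kept for oracle tests.

One integer seed drives every draw; the same configuration reproduces
byte-identical cohorts and outputs.

What the generator does **not** emulate: recombination within the gene,
population structure and relatedness beyond declared pedigrees, genotyping
error modes other than the two channels above, case-control ascertainment
bias, informative EHR missingness, and code-usage drift over calendar time.
Passing tests therefore demonstrate that the *procedure* is correct under
its stated assumptions — not that those assumptions hold in any particular
clinical dataset.

## Problem sizes used by the test suite

The suite phases 500 noise-free trios against transmitted-haplotype truth;
compares the EM against an exhaustive 1e-3 likelihood grid on 20-sample
fixtures; recovers `psiRec = 10` from 20 replicate cohorts of 60,000
singletons (requiring >= 90% CI coverage); and calibrates the null on 100
replicates of 10,000 singletons, where the exact test's rejection rate at
the 5% level is checked to stay near-or-below its nominal level, as
discreteness dictates. These sizes are the package's choices: large enough
that sampling noise cannot mask a logic error, small enough to re-run
routinely.

## Known limitations

* Phasing considers variant pairs; samples with three or more qualifying
  hets are summarised by their best-evidence pair.
* Population phasing assumes the unrelated set is homogeneous; structured
  cohorts can bias haplotype frequencies and hence posteriors.
* Association ignores relatedness (as in the reference analysis); the
  unrelated-subset filter is the only mitigation offered.
* The composite exposure pools the configured common risk alleles via
  diplotype calls on that subset; published composite tables built under
  unstated overlap rules need not match cell-for-cell.
* The PheWAS tests marginal 2x2 association per code group; it is not a
  phenome-wide regression with covariates.

## A minimal run

```{r run, eval = FALSE}
library(BiallelicBurden)
out <- runPipeline(pipelineConfig(
  sim = list(nTrios = 60L, nSingletons = 120L), seed = 1L),
  outDir = "pipeline-out")
out$cascade
out$association
out$burden
```
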