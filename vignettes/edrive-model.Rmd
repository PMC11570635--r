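---
title: "The e-Drive cage model: dynamics, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The e-Drive cage model: dynamics, inference, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(edriver)
library(dplyr)
```

## The system

`edriver` models a unitary self-eliminating CRISPR allelic drive (an
"e-Drive") in *Drosophila melanogaster*. The drive cassette — vasa-Cas9, a
single guide RNA against the insecticide-resistance allele, and a DsRed
marker — sits at the X-linked *yellow* locus. Its guide cleaves only the
*kdr* resistance allele 1014F of the voltage-gated sodium channel gene
(*vgsc*, a.k.a. *para*), ~50 cM away on the same chromosome. Cleavage in the
female germline is repaired either off the homologous wild-type 1014L allele
(conversion, rate `c`) or by end-joining into a loss-of-function allele we
label R (rate `l`). Because the cassette carries no guide against *yellow*,
it never copies itself: it segregates Mendelianly and its fate is decided
purely by selection on its host.

Two deployment modes differ only in the genetic background of the target
population. In **self-eliminating mode** the targets are wild-type *y⁺*, so
cassette-bearing (*y⁻*) males suffer the classic strong mating
disadvantage against *y⁺* competitors (`s_drive_self`, fitted 0.84) and the
transgene is purged while it drives. In **hover mode** the targets are *y⁻*,
the cost shrinks to a residual `s_drive_hover` (fitted 0.26), and the
cassette persists near its seeding frequency while converting resistance
alleles.

Three further forces act on the *para* locus:

* **Lethal mosaicism.** A zygote whose only *para* alleles are cleavable or
  destroyed cannot be rescued: drive-bearing males with 1014F, and
  drive-bearing females with F/F or R/F pairs, are inviable; R hemizygous
  males die regardless of the drive. This removes F-bearing X chromosomes
  from the population every generation.
* **Maternal Cas9 carryover.** Ribonucleoprotein deposited in the egg by a
  drive-bearing mother cleaves an inherited F allele with probability `m`
  (fitted 0.47). We model this as purely mutagenic (F to R): the zygote's
  access to a repair template is not assured, and cleavage-without-copying
  is the conservative reading of why extra F alleles disappear.
* **A recessive fitness cost of resistance.** F/F females are `s_Fhom`
  (fitted 0.56) less fecund. Optional per-copy carrier costs
  (`s_Fcarrier_f`, `s_Fcarrier_m`) are parameterized but default to 0: only
  the recessive cost has a published point estimate, so the default bundle
  contains exactly the fitted values.

## The recursion

Generations are discrete (the cage protocol is non-overlapping). Because the
two loci are ~50 cM apart we treat their inheritance as independent, and
female allele pairs are unordered (no cis/trans state). The genotype space
is small — 12 hemizygous male and 60 diploid female classes — so one
generation is computed exactly: mothers contribute offspring in proportion
to frequency x fecundity; each mother's mate is drawn in proportion to
frequency x mating weight (lottery polygyny, the simplest model consistent
with a mating-competitiveness cost); zygotes form at a 50/50 sex ratio,
maternal carryover is applied independently to every inherited F allele of a
drive mother's zygote, inviable classes are removed, and each sex is
renormalized. Pairs whose offspring die therefore contribute fewer recruits,
which is how lethal mosaicism exerts selection.

The stochastic simulator draws each next generation (`census_adults/2`
females and males, default 120 adults — the number seeded; the true progeny
census per bottle is unreported) i.i.d. from the exact next-generation
distribution. Extinction of all viable parents of either sex is a flagged
terminal state, never an error.

```{r trajectory}
pre <- cage_preset("self_elim_1to3")
tr <- run_deterministic(pre$config, pre$params)
tr
autoplot(tr)
```

Under the fitted point estimates the 1:3 self-eliminating cage loses the
DsRed cassette below 5% by generation 8 while the wild-type allele climbs to
roughly 80% by generation 9; hover cages keep the cassette and push 1014L to
fixation. These are the qualitative milestones the laboratory cages showed,
and the acceptance checks recompute them.

## The observation model

Each generation, half the adults are scored for DsRed (a hypergeometric
draw), and 25 randomly chosen flies are pooled for amplicon sequencing:
their X chromosomes (two per female, one per male) form the allele pool from
which `read_depth` = 5000 reads are drawn multinomially. This two-stage
scheme matters: 5000 reads from ~37.5 chromosomes carry ~37.5 chromosomes'
worth of information, and the fly-sampling stage produces the visible
extra-binomial scatter of the real per-generation allele frequencies.

## Inference

The likelihood treats the deterministic recursion as the mean process — the
single smooth curve fitted to replicate cages — with per-generation binomial
(DsRed tally) and multinomial (read counts) observation terms around it.
Parameters are sampled by random-walk Metropolis-Hastings on the logit
scale with Uniform(0,1) priors ("no prior information"), the Jacobian
included, and the constraint `c + l <= 1` enforced through the prior
support. Both mode-specific mating costs are fitted jointly: each dataset
carries its own design (mode, Cas9 activity), so self-eliminating and hover
cages inform `s_drive_self` and `s_drive_hover` inside one likelihood.

Two variance corrections are available and matter in practice:

* `read_ess` tempers the 5000-read multinomial to a chosen effective sample
  size (the overdispersion correction for the pooled-fly design;
  `1.5 * ngs_flies` = 37.5 is the natural value).
* `drift_adjust = TRUE` goes further and weights every generation's terms by
  quasi-likelihood factors `1/n / (1/n + t/N)` that add the cumulative
  finite-census drift variance (order `t/N` by generation `t`, census `N`)
  to the sampling variance. Every constant comes from the cage design; none
  is free. Without this adjustment the posterior treats genetic drift as
  parameter information and its credible intervals are overconfident; with
  it, interval coverage in repeat synthetic experiments is close to nominal.
  The plain multinomial remains the default so the bare reconstruction is
  what a user gets unless they opt into the corrections.

Numerical choices: proposal scale 0.15 on the logit scale (20-40%
acceptance on standard-size datasets); initial points drawn from the prior
and re-drawn (bounded retries) while the posterior is non-finite; chains
thinned by 10; summaries are empirical medians and 2.5/97.5% quantiles.

```{r fit, eval = FALSE}
data <- list(
  generate_cage_dataset("self_elim_1to3", n_cages = 2, seed = 1),
  generate_cage_dataset("hover_1to3", n_cages = 2, seed = 1001)
)
fit <- run_mcmc(data, mcmc_settings(iterations = 50000), drift_adjust = TRUE)
tidy(fit)
autoplot(fit)
```

## What the synthetic data emulate — and what they do not

`generate_cage_dataset()` reproduces the experimental designs exactly: the
15+15 vs 45+45 (1:3) and 30+30 vs 30+30 (1:1) seedings, homozygous founders
with the published haplotypes (cassette with 1014L; targets with 1014F),
half-population DsRed scoring, and the 25-fly / 5000-read two-stage allele
sampling, at a constant census of 120 adults. Ground truth (the noise-free
trajectory and the generating parameters) travels with each dataset so
recovery tests never re-derive it.

They do not emulate: overlapping generations or age structure, density
dependence, egg-laying dynamics within the 72-h window, mate-choice
structure beyond lottery polygyny, cis-linkage of cassette and target
alleles (free recombination at 50 cM is assumed from generation 1 onward),
or any laboratory artefact such as contaminated bottles. Passing recovery
tests therefore shows the inference machinery is correct and calibrated
*under the model's own assumptions*, not that the model captures every
feature of real cages.

## Amplicon classification

`classify_amplicon_reads()` is a deliberately small, deterministic
classifier, not a re-implementation of a full amplicon-genotyping pipeline:
it locates the 20-nt target window by fixed-length exact flank anchors
(default 15 nt, both orientations tried), calls L or F from the codon-1014
triplet when the window has reference length, calls NHEJ on any change of
anchor spacing (indel), and leaves everything else — including reads whose
codon matches neither variant — explicitly unclassified. Reported
frequencies are over classified reads, with the unclassified count always
alongside. The bundled reference (`synthetic_vgsc_reference()`) is
synthetic: the true amplicon sequence is not published, so the fixture uses
the canonical kdr codon change CTT (L) to TTT (F) as a convention, clearly
not a claim about the real sequence.

## Empirical cross estimators

For two-generation crosses the package provides the published closed forms:
`female_conversion_rate(Y) = 2 (Y - 0.5)` (half of F2-female reads come from
the reference paternal X), the x2 receiver-chromosome corrections of
`receiver_class_frequencies()`, and the exact binomial transmission-bias
test of `transmission_ratio()`. These are exact arithmetic identities plus
`stats::binom.test()`; negative conversion estimates are returned as
diagnostics rather than clamped away silently.

## Problem sizes used by the checks

The test suite and acceptance script run entirely on synthetic data at the
experimental scale: deterministic trajectories over 9-10 generations;
100-replicate stochastic bands at census 120; a 100,000-adult census for the
law-of-large-numbers check; one 50,000-iteration headline recovery fit on
2 + 2 cages; and a 20-repeat coverage study at 6,000 iterations per repeat
(a reduced-replication design — the headline chain length is reserved for
the single headline fit). Read-level checks use 10^2-10^4 reads.

## Known limitations

* The likelihood is a declared reconstruction; the original analysis'
  exact error model is not public. It is validated by parameter recovery
  and coverage, not by matching a reference implementation.
* Identifiability of `c`, `l` and `m` from cage trajectories alone is weak
  (their effects on allele loss overlap), which the wide published credible
  intervals for those parameters already indicate; expect broad posteriors.
* The non-drive viability of R/F females is not settled by the published
  crosses; it defaults to inviable (R is a loss-of-function allele of an
  essential channel, and balanced-line data show R is male-lethal) and is
  switchable via `r_female_lethal`.
* Carrier (genotype) frequencies are only conserved after the first
  generation of random mating — homozygous founders mix to Hardy-Weinberg
  proportions in one step, which is precisely the observed generation-1
  DsRed surge; allele frequencies are conserved exactly under neutrality.
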