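---
title: "Methods: dual stable-isotope-probing inference in dualsip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual stable-isotope-probing inference in dualsip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsip)
```

# The experiment this package analyses

Stable-isotope probing (SIP) feeds a microbial community an isotopically
labeled substrate and asks which organisms, lipids and metabolites become
enriched. `dualsip` targets incubations that combine two labels — `13C` on an
organic substrate or on dissolved inorganic carbon (DIC), and deuterium (D) on
the methoxy groups of an aromatic substrate such as veratric acid (VA) — and
read the outcome at three levels:

1. **DNA-SIP**: after CsCl isopycnic ultracentrifugation, labeled DNA bands at
   higher buoyant density. Per-fraction amplicon read counts are compared
   between labeled and control bottles with a ratio-of-odds-ratios statistic.
2. **PLFA-SIP**: compound-specific `δ13C` and `δD` of phospholipid fatty acids
   at the start and end of the incubation are converted to label-incorporation
   rates, and the dual-label ratio Ra/Rt classifies lipid production as
   heterotrophic or autotrophic.
3. **Metabolite SIP**: high-resolution MS peak lists are searched for `13C`
   and D isotopologue series; deuterium counts divisible by three reveal
   intact transfer of a trideuterated (CD3) methyl group.

# Isotope arithmetic

All internal mixing and rate computations use atom fractions
`F = R / (1 + R)`, with `R = R_std (1 + δ/1000)`; deltas exist only at I/O
boundaries. This matters because the rate formula below is linear in `F`, not
in `δ`. Reference ratios default to `R_VPDB = 0.0111802` and
`R_VSMOW = 1.5576e-4`, and exact masses to the IUPAC values, which reproduce
the isotopologue mass shifts of 1.0034 Da (`13C`) and 1.0063 Da (D) at
four-decimal rounding. All constants are overridable through
`sip_constants()` and are echoed into output headers.

PLFAs are measured as methyl esters; `methylation_correct()` removes the
derivatizing carbon (or its three hydrogens) by elemental mass balance
`δ_FA = ((n + a) δ_FAME − a δ_agent) / n`. The agent delta has no default: it
is an instrument-batch property the user must supply. Lipid hydrogen is
treated as non-exchangeable; no correction for exchangeable H is attempted,
which is the usual simplification for fatty-acyl hydrogen.

# DNA-SIP: the RoOR statistic

For one bottle, fractions are pooled into a *heavy* and a *light* side. The
default rule is a fixed density cut at 1.715 g/mL (`split_rule()`), with a
`top_k` alternative; the rule and threshold are recorded in every output,
because gradient screening practice varies between laboratories and a silent
difference here would silently move every downstream call. Counts are summed
within a side before forming the 2×2 table (taxon vs rest × heavy vs light) —
the simplest aggregation that respects sequencing depth.

The per-taxon statistic is

```
RoOR = OR_labeled / OR_control,   OR = (a/b) / (c/d)
```

with Haldane–Anscombe 0.5 pseudocounts applied only when a cell is zero, so
that zero-free tables stay exact. `RoOR > 1` suggests labeling; replicate
consensus requires 2/2 (duplicates) or 2/3 (triplicates) bottles.

**Read filter.** A taxon must carry at least 5 reads in the heavy pool and 5
in the light pool, pooled over labeled and control bottles (`per_side`, the
default). The stricter variant requiring 5 reads in all four pools separately
is available as `filter_scope = "per_pool"`, but it is not the default for a
structural reason: a strongly labeled, low-abundance taxon has essentially
*no* light-pool reads in the labeled bottle — complete labeling moves its DNA
~0.036 g/mL, several dispersion widths past the cut — so the four-pool rule
systematically rejects exactly the taxa the statistic exists to detect. The
pooled-side reading keeps the filter's purpose (suppressing sparse-count
artefacts) without that pathology.

**Null behaviour.** Under an exchangeable null (no labeling), the labeled and
control odds ratios are identically distributed, so for a duplicate design
with one shared control the probability that both replicates exceed the
control — i.e. a consensus false call — is the probability that the control is
the minimum of three exchangeable draws: 1/3, for any filter-passing taxon,
independent of read depth. The read filter is therefore the practical
false-positive control: it removes the (typically numerous) rare taxa from
consideration, and the package's null simulations show an overall false-call
fraction of roughly (filter-pass share) × 1/3. Users should treat RoOR > 1
as a screening rule and lean on the filter, the consensus and effect size
(RoOR ≫ 1) rather than on the bare inequality.

# PLFA-SIP: incorporation rates and Ra/Rt

For each lipid the label-incorporation rate is

```
rate = ΔF × C_produced / t        [pmol isotope L⁻¹ d⁻¹]
```

where `ΔF` is the excess atom fraction between Tend and T0 and
`C_produced = (conc_Tend − conc_T0) × n_C` is new lipid carbon. Negative
rates (lipid loss or isotope dilution) are clamped to zero by default and
flagged, since production is non-negative by construction; `clamp = FALSE`
preserves the raw value. For deuterium the formula is ambiguous about the
atom inventory: the package's default multiplies `ΔF(D)` by *carbon* produced
(both tracers expressed per unit of new biomass carbon, which keeps Ra and Rt
commensurable), and `d_inventory = "hydrogen"` instead uses the lipid's
hydrogen count from its parsed structure. The mode is recorded in outputs.

In dual incubations, Ra (the `13C` rate, inorganic-carbon assimilation) and
Rt (the D rate, total production) are each divided by the label strength of
their source pool before the ratio: the `13C` atom fraction of the DIC pool
(`dic_label_fraction()`: 500 mg of 99 atom% bicarbonate into 1 L of
groundwater with 4.5 mmol/L ambient DIC ≈ 0.57) and the D fraction of the
substrate's hydrogen (VA with two CD3 methoxy groups: 6 of 10 H = 0.6). This
normalization makes a pure autotroph read Ra/Rt ≈ 1; it can be disabled
(`normalize = FALSE`) to reproduce raw-rate ratios. Classification bands:
heterotrophic ≤ 0.3 (the established bound), autotrophic ≥ 0.8 (chosen as
"approximately 1" with room for measurement noise), mixed in between.
`acetogen_expectation()` encodes the two-carbon acetyl-CoA model: an acetogen
drawing a fraction `f` of acetyl carbon from a methyl group is expected at
Ra/Rt = 1 − f, hence 0.5 for the canonical Wood–Ljungdahl + methyltransferase
split.

PLFA names are parsed with the standard nomenclature (`16:0`, `a15:0`,
`cy17:0`, `10Me16:0`, `18:1ω7`). One convention needed fixing: mid-chain
methyl branches add a carbon beyond the chain number, so `10Me16:0` counts 17
carbons; hydrogen inventories follow CnH2nO2 minus 2 per double bond or
cyclopropane ring.

# Metabolite SIP: isotopologue series and the CD3 rule

`match_series()` searches peaks around a base feature on the
`(k13C, kD)` grid (`k13C + kD ≤ max_k`, default 12 — VA has 9 carbons and a
CD3-methoxy donor adds D in multiples of 3, so 12 covers plausible products)
at expected masses `base + k13C·1.003355 + kD·1.006277` Da. Full-precision
shifts from the mass table are used rather than their 4-decimal displays,
because matching at ppm tolerances cannot afford rounded constants.
Separating the two shift types at mass M needs resolving power
`M / 0.00292` (`required_resolving_power()`; ≈62,000 at veratric acid's
182.06 Da), which is why this is an orbitrap-class analysis.

Matching is deterministic: each peak may claim at most one grid point within
the ppm tolerance (default 2 ppm, a routine externally calibrated orbitrap
window); each grid point keeps its closest-ppm peak, ties broken by lower ppm
error then lower m/z. A peak within tolerance of *two* grid points is flagged
ambiguous and assigned to none — at the masses where carbon and deuterium
shifts approach the tolerance this prevents resolution-limited false CD3
calls, at the price of discarding the peak. Label flags additionally require
member intensity ≥ 1% of the base peak (`min_intensity_frac`, recorded in
outputs).

A feature whose maximum deuterium count is positive and divisible by three is
marked `cd3_transfer`, with `n_cd3_groups = max_kD / 3`: the signature of
intact enzymatic transfer of a trideuterated methyl group, as opposed to
scrambled biosynthetic D incorporation. Censuses (`count_label_census()`)
count distinct base features, not deconvoluted compounds — feature grouping
and adduct handling are upstream concerns.

# Synthetic data: what is emulated, what is not

The generators exist so that every decision rule can be exercised against
known truth without instrument data.

* `generate_gradient()` places each taxon's DNA at buoyant density
  `ρ = 1.66 + 0.098·GC + 0.036·label_af` g/mL with Gaussian dispersion
  `σ_ρ = 0.006` across a 12-fraction grid spanning 1.690–1.768 g/mL, and
  draws multinomial reads (optionally Dirichlet-multinomial) at 2,000 reads
  per bottle. The density model and full-labeling shift are standard SIP
  calibration values. Labeling is a single composite density-shift parameter
  per taxon, since density gradients cannot distinguish `13C` from D
  enrichment. Not emulated: gradient compression, fraction-volume drift,
  chimeras, taxonomic misassignment, compositional overdispersion beyond the
  optional Dirichlet term.
* `generate_plfa()` inverts the rate model exactly: it chooses Tend deltas so
  that at zero noise `incorporation_rate()` returns the configured
  per-producer rates to machine precision, then adds Gaussian delta noise
  (default 2 ‰). A producer's `phi` (0 heterotroph, 1 autotroph, 0.5
  acetogen) is recovered as its normalized Ra/Rt, which is what makes the
  closed-loop classification tests meaningful. Not emulated: chromatographic
  co-elution, derivatization offsets (the generator emits already-corrected
  deltas), lipid turnover during the incubation.
* `generate_peaklists()` emits the base peak plus isotopologue peaks at the
  configured label counts with multiplicative m/z jitter (default 0.3 ppm,
  lock-mass orbitrap accuracy). At several ppm of jitter the carbon/deuterium
  distinction collapses for masses above ~300 Da — adjacent grid points are
  only 2.9 mDa apart — and recovery degrades accordingly; this is a physical
  limit of the readout, not a tunable.

Passing closed-loop tests therefore demonstrates internal consistency of the
statistics under their own model assumptions, not robustness to every
real-data artefact listed above.

`sip_scenario()` bundles four study designs (single `13C`-VA with duplicate
bottles over 12 weeks; dual `13CO2`+D-VA triplicates over 12 or 5 weeks;
single `13CO2` duplicates over 5 weeks) with taxon and lipid casts evoking
the communities such incubations select for. The abundances, growth rates and
label assignments in the presets are invented fixtures with recorded ground
truth, chosen once as plausible values, not measurements.

# Numerical choices and problem sizes

* Odds ratios: pseudocount only on zero cells keeps textbook tables exact;
  an explicit pseudocount can be forced, and 0 with a zero cell is an error
  rather than an `Inf`.
* Degenerate gradients (uniform density, one-sided splits) error early with
  the offending rule echoed.
* Matching ties (equal ppm error) resolve by lower m/z so results are
  permutation-invariant.
* Rate inversion round-trips are asserted to 1e-9 relative at zero noise;
  delta→ratio→delta round-trips to 1e-9 ‰ over deltas up to 10⁶ ‰.
* The test suite simulates at modest sizes chosen to make sampling noise
  negligible relative to the asserted margins: 50–200 gradient simulations of
  6–40 taxa at 2,000 reads, 100 PLFA simulations, and 1,000-feature peak
  lists.

# Known limitations

* The RoOR>1 consensus rule has the irreducible 1/3 null false-call rate
  among filter-passing taxa derived above; the package reports effect sizes
  so users are not forced to rely on the bare threshold.
* No qSIP-style quantitative atom-fraction estimation from density shifts is
  attempted; the DNA layer is a presence/absence labeling screen.
* δD of incubation water is stored as metadata but no water-vs-substrate
  hydrogen source partitioning is computed; all lipid H is treated as
  non-exchangeable.
* Metabolite features are taken as given; compound identification beyond the
  user-supplied substrate mapping is out of scope.
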