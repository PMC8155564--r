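---
title: "Identifying cross-linked peptides from cleavable-linker MS2 spectra"
author: "xlms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cross-linked peptides from cleavable-linker MS2 spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlms)
```

## The problem

Chemical cross-linking mass spectrometry (XL-MS) covalently connects pairs
of residues — typically lysines — that are close in space, either within one
folded protein (intra-links) or across an interaction interface
(inter-links). After tryptic digestion, a cross-linked species consists of
two peptides joined by the linker, so a database search has to explain one
MS2 spectrum with *two* peptides. Enumerating all peptide pairs is quadratic
in the database and quickly becomes intractable for proteome-scale FASTA
files.

MS-cleavable linkers such as DSSO and DSBU solve this structurally: under
collisional activation the linker itself fragments asymmetrically, leaving a
*light* stump on one peptide and a *heavy* stump on the other. Because both
cleavage orientations occur in the ion population, each peptide ideally
appears as a pair of peaks — a **doublet** — separated by the fixed mass
difference

$$\Delta = m_\mathrm{heavy} - m_\mathrm{light}$$

(for DSSO $\Delta = 103.99320 - 54.01057 = 49.98263$ Da; at charge $z$ the
m/z spacing is $\Delta / z$). A doublet directly reveals the neutral mass of
the peptide that carries it:

$$m_\mathrm{pep} = m/z_\mathrm{light} \cdot z - z\,m_p - m_\mathrm{light}$$

with $m_p = 1.007276$ Da the proton mass. The search space then collapses
from all pairs to two independent, narrow mass windows.

## Detector: doublet finding and mass-pair hypotheses

`findDoublets()` scans all peak pairs and charge states $z = 1, \dots,
z_\mathrm{prec} - 1$ (a fragment cannot out-charge its precursor) for the
spacing $\Delta / z$ within the doublet tolerance (default 10 ppm, applied
to the heavier peak). Spectra with more than 2000 peaks are trimmed to the
2000 most intense first, bounding the quadratic pairing step.

Mass-pair hypotheses are formed in two modes, always constrained by the
precursor relation

$$\left| m_\alpha + m_\beta + m_\mathrm{XL} - M_P \right| \le T_D$$

where $m_\mathrm{XL}$ is the intact linker mass, $M_P$ the uncharged
precursor mass and $T_D$ the relation tolerance (default 5 ppm, convertible
to Da).

* **Evidence mode** requires ions from both peptides: either two full
  doublets, or one full doublet plus a lone peak that is consistent as the
  light *or* heavy stump ion of the inferred partner (both interpretations
  are tried at every charge; lone partners are searched among the 200 most
  intense unassigned peaks).
* **Indication mode** needs only one full doublet; the partner mass is
  inferred by subtraction from the precursor. The four light/heavy
  single-ion combinations of the inferred partner are matched purely as an
  annotation (`partnerIons`); emission does not require an observed partner
  ion. This is a deliberate design choice where the observable behaviour
  was open: requiring a partner ion would make indication mode a subset of
  evidence mode, which would defeat its purpose.
* **Combined mode** (the default) is the deduplicated union of both.

Diagnostic ions — linker fragments with no peptide attached — are matched
and reported as supporting annotation. They are advisory: a configured
strict flag can require them, but by default their absence never vetoes a
spectrum and their presence alone never admits one, since they indicate the
linker, not a specific peptide pair.

Monoisotopic precursor misassignment (picking the first isotope of a heavy
precursor) is handled by alternative precursor hypotheses at neutral-mass
offsets of $k \times 1.0033548$ Da, $k = 0, -1, \dots$; two offsets are
considered by default, either assumed blindly or verified against a
supplied MS1 scan.

## Search: binomial peptide scoring and pair selection

Candidates for each hypothesized peptide mass are fetched from a
mass-sorted index of digested peptides (tryptic, cleavage after K/R but not
before P, up to 2 missed cleavages, lengths 5–30, fixed
carbamidomethyl-C and variable oxidation-M up to 2 per peptide — all
overridable). A residue is a valid link site when it is linker-reactive and
not the C-terminal residue of the peptide (a cross-linked lysine cannot be
cleaved by trypsin), except at the protein C-terminus. The candidate query
tolerance defaults to 20 ppm evaluated at the *precursor*-mass scale and
applied as an absolute Da window: a doublet-derived mass inherits the
absolute m/z error of a centroid at the (heavy) peptide's m/z, and a
partner mass inferred by subtraction inherits the absolute error of the
*other* peptide's doublet — for a light partner of a heavy peptide that
error can be many ppm of the partner's own mass, so a window proportional
to the partner mass would be the wrong scale.

Each candidate is scored at every valid link site against the spectrum.
Theoretical b/y ions are generated at charges 1–2; fragments containing the
link site are emitted twice, once with the light and once with the heavy
stump mass (cleaved species dominate stepped-HCD spectra, so fragments
carrying the intact linker plus the whole partner peptide are off by
default behind a flag). With $n$ theoretical ions, of which $k$ fragment
identities matched (either stump variant counts once), the chance
probability of the match is the binomial tail

$$P = \Pr(X \ge k \mid n, p), \qquad
p = \mathrm{clamp}\!\left(\frac{2\,n_\mathrm{peaks}\,\tau}
{m/z_\mathrm{max} - m/z_\mathrm{min}},\ 10^{-6},\ 0.5\right)$$

where $\tau$ is the fragment tolerance in Da (a ppm tolerance is evaluated
at the centre of the spectrum's m/z range — the clamp bounds and this
evaluation point are this package's numerical choices). The peptide score is

$$S = \max\bigl(0,\ -\log_{10} P \cdot f_\mathrm{explained}\bigr)$$

with $f_\mathrm{explained}$ the matched fraction of total ion intensity.
The score of a peptide *pair* is conservative: the minimum of the two
peptide scores, so a pair is only as credible as its weaker half. For each
hypothesis the top-5 candidates per mass are paired, pairs violating the
precursor relation are discarded, and the best pair over all hypotheses is
kept — exactly one result per spectrum. Ties are broken deterministically:
higher summed explained intensity, then target over decoy (TT, TD, DD),
then lexicographic sequence order. A peptide may pair with itself only if
it occurs at least twice in the database, or when homodimer searching is
explicitly enabled.

## Validation: two-level target-decoy FDR

Decoys are full sequence reversals, one per target, under the reserved
`REV_` accession prefix; a peptide found in both target and decoy space
counts as target (conservative: it inflates the decoy-based FDR estimate
rather than deflating it). A CSM is a decoy hit when *either* peptide is a
decoy (TD and DD both count as decoy).

CSMs that resolve to the same unordered pair of absolute protein residues
are merged into one **cross-link** — this also merges CSMs whose peptides
are substrings of one another, since the absolute link position coincides.
A shared peptide that maps to several proteins joins every residue pair it
supports; a cross-link whose accessions can be read as both intra and
inter is classified intra (conservative for interaction claims). The
cross-link score is the maximum member CSM score.

FDR is estimated independently at the CSM and the cross-link level by a
descending-score scan with the estimator $\mathrm{FDR} = D / T$, following
the assumption that false positives are no more numerous than decoys (the
$(D+1)/T$ variant is available as a config switch; whether DD hits should
be subtracted TD−DD-style is left to the plain $D/T$ reading). Tied scores
pass or fail as a whole group. Two thresholds, 1% and 5% by default, yield
`high` and `medium` confidence labels; the 1% set is a subset of the 5% set
by construction. Optional intra/inter separation validates the two classes
independently and reconcatenates them, so inter-link noise cannot displace
intra-link labels (and vice versa).

## The synthetic-spectrum generator

Every test in the package runs against generated data, so the generator is
first-class, seeded, and byte-for-byte reproducible. It emulates:

* random target proteins (default 20 × 300 residues) over a lysine-boosted
  alphabet so most tryptic peptides carry a link site; C and M are excluded
  so planted peptides carry no variable modifications and the ground truth
  stays free of modification bookkeeping;
* per spectrum, two linkable tryptic peptides with a unique database
  location (so the true residue pair is well defined), a precursor charge
  drawn from {3: 0.50, 4: 0.35, 5: 0.15} (cross-linked precursors are
  predominantly 3+ and higher), and a precursor mass computed exactly from
  the mass relation;
* both stump doublet peaks per peptide with probability 0.9 each, at a
  fragment charge of 1 or 2;
* b/y ladders at charge 1, each theoretical ion (stump variants are
  separate ions) planted independently with probability `coverage`
  (default 0.7);
* Poisson(50) uniform noise peaks, log-normal intensities
  ($\mu = 10$, $\sigma = 1$, arbitrary units) shared by signal and noise,
  Gaussian 5 ppm m/z error on planted peaks, and a 5% chance of recording
  the +1-isotope precursor;
* an entrapment database of residue-shuffled target copies (4× by
  default), re-shuffled until tryptic-peptide-disjoint from the targets.

The precursor m/z itself is written exactly (apart from deliberate isotope
misassignment): instrument precursor estimates come from MS1 isotope
fitting and are systematically better than single-centroid MS2 jitter, and
this keeps the precursor-relation tolerance meaningfully tight.

What the generator does *not* emulate — isotope envelopes, correlated
fragment intensities, co-isolated chimeric precursors, dead-end and loop
links, retention-time structure, profile peaks — bounds what passing tests
prove: they validate the bookkeeping, the search logic and the statistical
calibration of the engine, not its ranking performance on real instrument
data.

## Numerical choices and degenerate inputs

* Monoisotopic residue masses from the standard IUPAC table; proton
  1.007276 Da; C13−C12 = 1.0033548 Da; water 18.0105646863 Da.
* Peak-match ties (two peaks equidistant within tolerance) go to the more
  intense peak.
* Hypothesis deduplication key: masses rounded to 3 decimals, canonical
  order $m_\alpha \ge m_\beta$.
* Missing precursor charge: charges 2–6 are enumerated and the best CSM
  over all assumptions is kept.
* Empty spectra, empty databases, spectra without doublets, and
  single-residue peptides all yield empty (not error) results; malformed
  MGF blocks raise errors naming the offending scan.
* Default problem sizes in the test-suite runs: simulated worlds of 2–20
  proteins and 10–500 spectra, chosen so a complete run of the suite stays
  in the minutes range on one core while the 500-spectrum run exercises
  the full pipeline at the generator's default conditions.

## Worked example

```{r example, eval = FALSE}
params <- simulationParams(seed = 1)
db <- generateDatabase(params,
                       targetPath = "targets.fasta",
                       entrapmentPath = "entrapment.fasta")
sim <- generateSpectra(db, params, mgfPath = "spectra.mgf",
                       truthPath = "truth.tsv")

res <- runSearch("spectra.mgf", "targets.fasta", runConfig(),
                 outDir = "results")
res$tallies
exportXiview(res$crosslinks, res$csms, "xiview.csv",
             minConfidence = "high")
```

## Known limitations

* The per-peptide score is a faithful reconstruction of a
  binomial-probability match score from its published qualitative
  description (chance probability from the binomial tail, weighted by
  explained intensity, log-transformed); absolute score values are
  therefore not comparable to any other implementation, only the ranking
  behaviour is.
* Dead-end (mono-link) and loop-link species are out of scope; spectra of
  such species are either rejected or, rarely, mis-explained as
  cross-links and must be controlled by the FDR.
* Non-cleavable linkers require the quadratic all-pairs search that this
  engine exists to avoid and are not supported.
* FDR estimates with few decoys (small databases, few spectra) are
  granular; the $D/T$ estimator is only meaningful when decoy counts are
  not trivially zero.
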