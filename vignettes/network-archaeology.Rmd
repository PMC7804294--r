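---
title: "Network archaeology of ribosomal protein interactomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network archaeology of ribosomal protein interactomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RiboArch)
```

This vignette is the package's own account of the model and procedure it
implements, the parameters that matter, the numerical choices made, and
what the synthetic study conditions do and do not establish.

## 1. Interfaces as buried surface area

The operational definition of a protein–protein interaction here is
*buried solvent-accessible surface area* (SASA). For a chain pair (A, B),

$$\mathrm{buried}(A,B) = \mathrm{SASA}(A) + \mathrm{SASA}(B) -
\mathrm{SASA}(A \cup B),$$

each term computed over the pair's atoms only. This sums both sides'
losses; the convention is recorded in the output so downstream consumers
cannot silently drop a factor of two. A pair counts as contacting when
the buried area exceeds `burialTol`, and a residue belongs to the
interface when its own SASA loss exceeds `burialTolRes`.

SASA is computed Shrake–Rupley style: each atom inflated by the probe
radius, test points distributed on the inflated sphere, a point counted
accessible when outside every neighbouring inflated sphere.

Parameters, defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| `probe` | 1.4 | Å | water probe radius, the field's convention |
| `nPoints` | 960 | points/atom | golden-spiral quadrature; error on an isolated sphere is below 0.1%, and buried areas on toy complexes agree with a 10^6-point Monte Carlo recomputation to well under 2% |
| `burialTol`, `burialTolRes` | 0.1 | Å² | suppress quadrature noise; with 960 points the noise floor on a pair difference is far below 0.1 Å² |
| vdW radii | Bondi-style table | Å | shipped table (`vdwRadius()`); unknown elements fall back to a configurable default with a warning |

Numerical choices: the sphere points come from a deterministic
golden-spiral (Fibonacci) construction, so identical inputs give
bit-identical areas on any platform. Points exactly on a neighbour's
surface count as buried, so duplicated (coincident) atoms contribute
zero area instead of a noise-dependent sliver. Altloc records keep the
highest-occupancy conformer; hydrogens are dropped (deposited ribosome
structures generally lack them); author residue numbering is preserved
verbatim with insertion codes folded into the residue key. Chain pairs
whose atoms can never be within $r_i + r_j + 2\,\mathrm{probe}$ are
skipped without SASA evaluation, which is what makes all-pairs scans of
many-chain structures cheap.

We deliberately do not reproduce any particular legacy SASA program
bit-exactly: radii tables and quadratures differ between
implementations, so the contract is tolerance-based agreement with an
independent dense-sampling oracle, enforced in the test suite.

## 2. Protein anatomy and centres of mass

Each r-protein decomposes into a globular domain and *extensions* —
protruding segments classified as segment, mix (segment + α-helix),
α-helix, loop or β-hairpin, attached N-terminally, C-terminally or
internally. These boundaries and the evolutionary statuses (U/A/B/E for
proteins; Ub/Ua/Ue/Ae for extensions acquired by an older protein at a
later transition) are *inputs*, supplied as an annotation table — they
come from expert structural curation, which the package does not try to
automate. Validation is strict: inverted or overlapping ranges, unknown
categories, extension statuses inconsistent with the host protein's
status, and annotation chains absent from an attached structure are all
errors.

Node positions are the centre of mass of the globular domain, or of the
whole protein when no globular domain exists. The COM is geometric
(unweighted over heavy atoms): mass weighting changes protein COMs by
fractions of an Å while requiring an element-mass table; the choice is
recorded in the graph metadata and a `weights` argument exists for the
weighted variant.

Extension lengths count modelled residues only — statistics are taken
over what is visible in the structures, so disordered termini do not
inflate the size distribution.

## 3. The network graph

Nodes are proteins and the six functional sites (PTC, tunnel, mRNA,
tRNA-A/P/E). Component-level contacts aggregate into one edge per node
pair; the multiplicity survives as `n_connections`. Edges carry a
contact type; when one side of a structure-derived interface spans both
globular and extension residues, the side is attributed to the
component burying the larger summed ΔSASA, with ties going to the
extension (extensions being the objects under study, a tie should not
silently vanish into the globular bin). Site–site connections
(tRNA–mRNA geometry and the tRNA arms reaching the PTC) are kept in the
drawn graph — and therefore in centrality computations — but flagged
`excluded_from_stats`, so connectivity statistics never count them.

Functional modules follow the site categories a protein touches (the
three tRNA sites count as one category): one category makes a module
member, two a 2-way bridge, three a 3-way bridge; a protein with no
site contact whose protein neighbourhood spans both subunits is a
subunit bridge. The mRNA is a single node; at the coarse-grained scale
of a COM graph there is no defensible way to split it.

## 4. Archaeology

Cross-kingdom identity is by unified nomenclature name, so the
universal core is simply the intersection of the three kingdoms' edge
key sets. Both the aggregated pair count and the component-level
contact counts are reported, because the two can differ whenever a core
pair gains reinforcing contacts in one kingdom.

Transition statistics treat the parent network's component-level
contact set as the baseline: a child contact is *new* when its
(pair, component-pair) key is absent from the parent, which correctly
counts reinforcements of existing pairs as new contacts. Status-pair
fractions are computed over new protein–protein contacts, while the
functional-site fraction uses all new contacts as its denominator — the
two cannot share a denominator, since a U-B pair has two protein
endpoints by definition. Contacts whose two components both carry the
transition's acquisition status (B/Ub; A/Ua; E/Ue/Ae) are reported as
coevolved. Percentages are rounded to integers only at reporting time.

## 5. The Erdős–Rényi randomness test

The null hypothesis is that the observed network is a typical
realisation of an Erdős–Rényi random graph. We condition on the
observed size and density by using G(n, m) with matched node and edge
counts, removing density as a nuisance dimension. Because the law of a
centrality statistic under this null has no usable closed form, the
test is Monte Carlo: sample `nSamples` null graphs, compute the
statistic family, and report the add-one empirical upper-tail p-value
$(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(\mathit{nSamples}+1)$,
which can never be zero.

The default family measures centrality concentration: maximum
betweenness, betweenness variance, the inverse participation ratio of
the eigenvector-centrality vector, and degree variance. *Coherence* is
operationalised as unanimous rejection across the family — a
conservative rule that needs no multiple-testing correction (per-
statistic p-values are also reported raw). This unanimity rule is an
approximation of a formal coherence notion and is labelled as such in
the outputs.

Two numerical choices matter. Eigenvector centrality is computed from a
dense symmetric eigendecomposition rather than a randomly started
iterative solver, so the test is bit-reproducible for a fixed seed.
And the RNG state is sandboxed: running the test does not perturb the
caller's random stream.

The key statistical property — type-I error calibration — is tested
directly: drawing the "observed" graph from G(n, m) itself, the
rejection rate of the maximum-betweenness statistic over 200 replicates
at α = 0.05 must fall inside the binomial 95% confidence interval (ties
in a discrete statistic can only make the add-one rule conservative).

## 6. Conservation and aromatic acquisitions

A column is *strictly* conserved when one residue occurs in more than
the threshold fraction (default 0.80) of sequences, and *similar*-
conserved when one amino-acid class does: aromatic {F, Y, W, H}, basic
{K, R}, acidic {D, E}, polar {S, T, N, Q, C}, hydrophobic
{A, V, L, I, M, G, P}. Histidine sits with the aromatics because that
is how aromatic acquisition maps treat it. Gaps count in the
denominator — a column 90% identical among non-gap rows but half-gapped
is *not* conserved; this is the stricter reading of "more than 80% of
the sequences", and all-gap columns are flagged and never conserved.
Both strict and similar flags are carried everywhere, so consumers can
choose either rule.

Comparing an archaeal and a eukaryotic profile through a column map
classifies conserved aromatic columns of the eukaryotic alignment as
`new_in_E` (not conserved aromatic in archaea), `ancient` (conserved in
both) or `strengthened_similar_to_strict` (class-conserved in archaea,
strictly conserved in eukarya).

π-interaction geometry is centroid-based with class cutoffs: π–π ≤ 7.0 Å
(ring centroids), cation-π ≤ 6.0 Å (Lys NZ / Arg CZ), anion-π ≤ 5.5 Å
(Asp CG / Glu CD), proline-π ≤ 6.0 Å (proline ring centroid). The
literature uses a range of thresholds; these sit in the commonly used
middle and are all config-exposed (`piCutoffs()`). Each aromatic
reports its nearest qualifying partner per class; π–π pairs are emitted
once under a deterministic ordering; incomplete rings are skipped with
a warning. A separate closest-approach scan (default window 10 Å)
reports "distant approach" motifs where two extensions face each other
without burying area.

## 7. The synthetic study conditions

Every stage is exercised on seeded generators whose defaults *are* the
study conditions, with machine-readable ground truth:

- `makeToyComplex()`: ideal poly-alanine helices (rise 1.5 Å, 100°
  twist, five heavy atoms per residue) at controlled separations,
  written in both PDB and mmCIF dialects, with the planted
  contact/no-contact truth. Ideal helices are the simplest geometry
  with realistic atom packing for SASA work.
- `makeAnnotatedNetwork()`: supplementary-style kingdom contact tables,
  annotations and node coordinates planting a 49-edge universal core
  with 45% of its contacts on functional sites; a bacterial transition
  of 100 new protein–protein contacts split 58/19/12/9/2 across
  U-B/B-B/Ub-U/Ub-B/other plus 16 functional contacts (14% of 116); an
  archaeal transition split 47/19/23/11 (U-A/A-A/Ua-A/Ua-Ua — the
  Ua-mediated share is 34%, one point under the 35% it emulates,
  because 47 + 19 + 35 exceeds 100 after rounding) plus 4 functional
  contacts (4%); a eukaryotic transition with 57% of new contacts
  mediated by Ue/Ae extensions, 11 incoming proteins and 2 functional
  contacts (2%); eukaryotic network contact types of 115/255 ext-G
  (45%) and 99/255 ext-ext (39%); extension-size fractions above 80 aa
  of exactly 1%, 2%, 4% and 10% for the ABE/B/A/E sets; two
  multiplicity-2 pairs in the bacterial network; coevolution showcases
  (uL5/uL13/uL23 extensions paired with incoming bacterial proteins,
  uL4–uL24 in archaea, tripartite eL13/eL15→uL4 and eL13/eL18→uL15 in
  eukarya; eL15 ends up bridging PTC, tunnel and a tRNA site). Node
  coordinates place proteins on subunit shells whose radius grows with
  evolutionary recency, and later-stage contacts between ancient
  proteins are drawn from the most distant candidate pairs, so the mean
  COM distance of newly added edges increases monotonically along
  core → B → A → E by construction with a wide margin.
- `makeMsa()`: paired archaea/eukarya alignments (60 sequences × 120
  columns by default) with planted strict, ancient-aromatic,
  new-aromatic and strengthened columns at exactly 90% occupancy;
  background columns are uniform over the 20 residues, so the
  probability that one crosses the 80% rule by chance is below
  10^-15 per column. Gaps are planted only in background columns.

Network wiring choices worth knowing: all cross-subunit communication
in the planted graphs flows through the tRNA/mRNA site edges and the
PTC, which is what makes the PTC the betweenness maximum in all three
kingdom graphs — the architecture the analysis is meant to detect. The
three showcase proteins keep only their scripted edges so their module
labels and centralities are stable across seeds. Partner sampling is
otherwise near-uniform, with one consequence stated honestly: the
planted degree sequences are close to Erdős–Rényi, so the
degree-variance statistic of the null test does not reject on these
fixtures even though every centrality statistic does.

What passing on these conditions shows — and what it does not. It shows
the machinery is correct: planted proportions, cores, multiplicities,
module labels, conserved columns and distances are recovered exactly,
and the geometric and statistical engines agree with independent
oracles. It does not show anything about real ribosomes: the toys have
no rRNA, no experimental noise, no missing density, no paralog
ambiguity, and their interface sizes and degree distributions are
idealised. Analysing real structures requires deposited coordinate
files, curated annotations and alignments as inputs.

## 8. Problem sizes and known limitations

The shipped tests and the acceptance script run on deliberately small
problems: toy complexes of 60–120 atoms (with a 10^6-point Monte Carlo
SASA oracle on a 100-atom complex), kingdom networks of 55–77 nodes and
~200–260 edges, null tests of 199–999 samples, and a 200-replicate
type-I calibration — minutes of single-CPU compute in total.

Limitations: no symmetry-mate expansion and no hydrogen addition in
interface detection; contact detection at chain-pair level attributes
one component pair per structural interface (component-level
multiplicity comes from the curated tables); no inference of
evolutionary status or extension boundaries from sequence/structure;
no degree-preserving (configuration-model) null — the stated null is
Erdős–Rényi, and conditioning further on the degree sequence would
answer a different question; alignment construction is out of scope
(alignments are inputs).
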