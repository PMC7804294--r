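# RiboArch

Evolutionary archaeology of ribosomal protein (r-protein) interaction
networks.

## The problem

Mature ribosomes are laced with a network of tiny protein–protein
interfaces: the globular domains (G) and long filamentous extensions
(ext) of the r-proteins touch each other and the ribosome's functional
sites — the peptidyl transferase centre (PTC), the peptide exit tunnel,
the mRNA channel and the three tRNA sites. Comparing the bacterial (B),
archaeal (A) and eukaryotic (E) ribosomes lets one excavate how this
interactome grew: which connections are universal (ABE), which were
acquired at each evolutionary transition (ABE→B, ABE→A, A→E), whether
extensions were acquired *in concert* on both sides of a new interface
(coevolution), and whether the resulting graphs look anything like
random graphs.

RiboArch is for structural and evolutionary systems biologists who want
that analysis as a reproducible pipeline rather than a collection of
one-off scripts.

## What it computes

- **Interface detection by SASA difference.** A contact between chains
  A and B is the solvent-accessible surface area buried on complexation,

  `buried(A,B) = SASA(A) + SASA(B) − SASA(A ∪ B)`,

  computed with a Shrake–Rupley engine (probe 1.4 Å, deterministic
  golden-spiral quadrature, Bondi-style van der Waals radii). Interface
  residues are those with ΔSASA above a burial tolerance.
- **Centre-of-mass networks.** Undirected graphs whose nodes are
  r-proteins (COM of the globular domain, or of the whole protein when
  no globular domain exists) and functional sites; edges carry the
  contact type (ext–ext, ext–G, G–G, ext–funct, G–funct), the
  evolutionary status pair of the contacting components (U-B, Ub-U,
  Ua-Ua, …), the multiplicity of component-level contacts and the COM
  distance.
- **Network archaeology.** Universal-core intersection across the three
  kingdoms, per-transition statistics of newly acquired contacts,
  functional-site contact fractions, coevolved contact pairs,
  extension-size statistics (fraction above 80 aa), and the COM-distance
  trend of newly added edges.
- **Graph statistics.** Degree, betweenness (BC), eigenvector (EV) and
  closeness centralities; a Monte Carlo test of non-randomness against
  the Erdős–Rényi G(n, m) null with empirical upper-tail p-values
  `p = (1 + #{null ≥ observed}) / (nSamples + 1)` over a family of
  centrality-concentration statistics.
- **Conservation mapping.** Per-column alignment conservation under the
  "more than 80% of sequences" rule (strict identity vs amino-acid-class
  similarity), interface conservation fractions, detection of newly
  conserved aromatic residues in eukaryotes (new / ancient /
  strengthened similar→strict), and geometric classification of π–π,
  cation-π, anion-π and proline-π interactions.
- **Seeded synthetic data.** Generators for toy poly-alanine complexes
  (PDB and mmCIF), supplementary-style annotated kingdom contact tables
  with planted ground truth, paired alignments with planted conserved
  columns, and ER graphs — so the whole pipeline is testable offline.

## Worked example

```r
library(RiboArch)

net <- makeAnnotatedNetwork(file.path(tempdir(), "demo"), seed = 1)

transitionStats(net$graphs$ABE, net$graphs$B, "ABE_to_B")
#> Transition ABE_to_B: 116 new contacts on 114 new pairs, 18 new proteins
#>   status pairs: U-B 58%, B-B 19%, Ub-U 12%, Ub-B 9%, U-U 2%
#>   functional-site fraction of new contacts: 13.8%

universalCore(net$graphs[c("A", "B", "E")])$n_edges
#> [1] 49

centralities(net$graphs$E, giant = TRUE)
#> Centralities on 77 nodes / 261 edges
#>   argmax: degree=uS12, betweenness=PTC, eigenvector=uS12, closeness=PTC

erNullTest(net$graphs$E, nSamples = 999, seed = 1)
#> Erdos-Renyi G(77, 261) null test, 999 samples (seed 1)
#>  statistic    observed     p reject
#>     bc_max 0.400347396 0.001   TRUE
#>     bc_var 0.003409763 0.001   TRUE
#>    ev_conc 0.046582338 0.001   TRUE
#>    deg_var 7.016404648 0.180  FALSE
#> coherent rejection at alpha = 0.05: FALSE
```

Reading the output: the bacterial transition is dominated by contacts
between universal and incoming bacterial proteins (58% U-B), the three
kingdom networks share a 49-edge universal core, the betweenness
maximum of the eukaryotic network sits on the PTC node, and the
centrality-concentration statistics reject the Erdős–Rényi null at
p = 0.001 (the degree-variance statistic does not — the synthetic
network's degree sequence is deliberately ER-like; see the vignette).

The full pipeline (`runPipeline("config.yaml")`) chains structure
parsing, interface detection, network building, archaeology, graph
statistics and conservation mapping, and writes GraphML/TSV exports and
a JSON summary. A thin command-line wrapper lives in
`inst/scripts/riboarch.R`.

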