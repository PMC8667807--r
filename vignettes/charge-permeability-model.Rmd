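---
title: "The charge-permeability model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The charge-permeability model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcharge)
```

## The model and its assumptions

AMPA and NMDA receptors are tetramers; each subunit's M2 re-entrant loop
places one residue at the narrowest part of the pore, and together these
four residues form the selectivity filter. Where that residue has a polar
uncharged side chain (asparagine, glutamine, serine, threonine), its
electronegative oxygen presents a partial negative charge (δ−) to the pore
lumen. The model promotes each δ− to a full elementary charge, so the filter
carries an integer **ring charge** `r_q ≤ 0` fixed entirely by subunit
composition: four asparagines (GluN1/GluN2 NMDARs, or the glutamines of
GluA2-lacking AMPARs) give `r_q = −4`; each glycine-bearing GluN3 or
arginine-bearing edited GluA2 removes one unit.

Permeation of an ion with signed charge `q_i` is a product of two binary
gates. *Charge attractivity* `A = 1 iff |r_q + q_i| > 0` fails only when the
entering ion would exactly neutralise the ring — a single ring charge per
ion species (−1 for monovalent cations, −2 for divalent). *Inward drive*
`B = 1 iff q_i + |r_q + q_r| > q_r` asks whether the entering ion's charge,
aided by the ring charge left unneutralised by the resident ion (`q_r`; 0
for an empty pore), exceeds the resident's charge and can push it inward.
The model is deliberately qualitative: its output is a bit, not a flux. It
assumes a fully activated receptor, ignores membrane potential,
concentration gradients, Mg²⁺ block and desensitisation, and treats ions as
bare charges — which is why Mg²⁺ and Ca²⁺ (and K⁺ and Na⁺) are
indistinguishable to it, and why it is a screening model for selectivity
rather than a conductance model.

## From single verdicts to channel selectivity

A verdict describes one displacement event. Channel-level selectivity is a
property of the sequence of occupancies: we build a directed graph whose
states are `EMPTY` plus one occupied state per ambient ion, with an edge
`s → i` exactly when the verdict lets ion `i` enter from state `s`. `EMPTY`
is never re-entered — permeation is displacement with immediate
re-occupation, consistent with ions being transiently trapped and held in
the filter — so `EMPTY` is at most a start state.

The narrative notion "once the pore holds Ca²⁺ it admits only Ca²⁺" is
formalised minimally as absorption: the terminal strongly connected
components of the reachable graph are where the channel spends its long run.
An ion is **unconditionally** permeable if it enters from every state,
**steady-state** permeable if it enters from every state of every terminal
class reachable from `EMPTY`, and **conditional** if it enters from some but
not all states. With several terminal classes the steady-state flag is the
conservative intersection (permeable in all of them), with per-class detail
kept in an attribute — an explicit tie-break rather than an arbitrary one.
Exotic ambient sets can produce several terminal classes; the default
cation pair never does.

```{r}
selectivity_profile(c(-4, 0))
```

The profile exposes both semantics because a binary permeability-vs-ring-
charge plot can be read either way; the steady-state column is the default
interpretation since it matches the occupancy narratives at `r_q = −3`
(Ca²⁺-selective) and `−1` (Na⁺ loses attractivity). Both cations are fully
permeable only at the full (−4) or ablated (0) ring; rings beyond −4
(hypothetical pentamers/hexamers) screen nothing, and the scan range is
hard-capped at −8 to keep outputs finite while covering every documented
claim (the chloride threshold at −6 being the deepest).

## Parameters that matter

* **Residue contributions** (unitless elementary charges): N/Q/S/T → −1,
  everything else → 0. Positively charged R and K contribute 0, not +1 —
  counterintuitive but forced jointly by two fixed points: incorporating two
  edited GluA2 subunits moves `r_q` from −4 to −2, and the all-edited
  homomer sits at 0. Acidic D/E never occur at a filter position in the
  reference set; they map to −1 (a full charge, consistent with partial
  charges being promoted) and warn that this is an extrapolation.
* **Stoichiometry**: assemblies default to n = 4; other n-mers require
  `hypothetical = TRUE`. Non-native combinations (NMDAR without GluN1,
  NMDA/AMPA mixtures) warn but evaluate, since the model operates on any
  residue ring and heterologous systems express such combinations. Subunit
  order is preserved for display only; the ring is a permutation-invariant
  sum.
* **Alignment scoring** (anchoring): match +1, mismatch −1, linear gap −2
  with end gaps penalised; identity floor 0.30; length cap 2000. All are
  overridable via a `key = value` config file. The scheme was chosen for
  determinism and oracle-checkability over a substitution matrix: anchoring
  targets a 21-residue fragment, where a BLOSUM-style matrix adds nothing
  but platform-dependent tie structure.

## Numerical and degenerate-input choices

All core quantities are exact integers; there is no floating point anywhere
in the model, hence no tolerances. Queries with `r_q > 0` are rejected (the
filter is never net positive, and the anion reasoning depends on it), as are
non-integer charges. The empty pore is encoded as resident charge 0.
Alignment traceback ties are broken with the fixed move precedence
diagonal > up > left, making anchored coordinates bit-reproducible across
platforms; 1-based coordinates match the field's residue-numbering
convention (N598, Q605, N614). A filter column that aligns onto a query gap
returns an explicit `NO_HOMOLOGOUS_RESIDUE` flag rather than a nearest
position; a too-narrow anion scan returns "undetermined within range"
rather than extrapolating a threshold.

## What the synthetic fixtures emulate — and what they don't

The M2 fragments shipped with the registry are **synthetic stand-ins**
(`inst/extdata/m2_fragments_synthetic.tsv`): 21-mers that embed each
subunit's documented filter residue at a known offset in an M2-like context,
similar within a receptor family, divergent between families. They make the
anchoring pipeline fully testable offline — self-anchoring, cross-family
projection (a GluN3 query against the GluN1 reference lands on glycine),
mutants, deletions and shuffled decoys — but they are not the UniProt
sequences, so anchored *positions* on real sequences should be interpreted
via the registry's printed residue numbers, not via these fragments.
Likewise the fixture generator draws flanks uniformly over the 20 standard
residues: composition realism is irrelevant to the coordinate and
identity-floor contracts being tested, and passing those tests says nothing
about alignment quality on genuinely divergent real M2 domains. Ring-charge
predictions never depend on the fragments — only on the residue identities,
which are the documented ones.

Decoys are composition-preserving shuffles of real fixture sequences,
chosen to stress the identity floor specifically (same length, same residue
usage, destroyed positional signal).

## Problem sizes

Every quantity in the package is desk-scale: grids of at most 9 ring
charges × a handful of ion charges, occupancy graphs of ≤ 4 states, a
1365-row tetramer-multiset roster, and alignments of ≤ ~50 residues. The
full test suite, including the exhaustive-enumeration alignment oracle at
length ≤ 8 and the brute-force reachability oracle over all ring charges
and ion subsets, runs in well under a minute on one CPU.

## Known limitations

Binary output only: no permeability ratios, reversal potentials, GHK flux,
kinetics or dwell times. No geometry — pore radius, hydration, and the
arrangement of subunits around the ring (1-2-1-2 vs 1-1-2-2) are invisible
to a charge sum. Fractional (δ−) charges are promoted to full charges; a
graded-charge variant would shift thresholds and is deliberately out of
scope. K⁺ is provided for convenience but carries no K⁺-specific behaviour.
The anchoring step is pairwise, not a multiple alignment: it reproduces
homologous-column logic at single-query scale but makes no attempt to
reproduce any particular MSA's column numbering.
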