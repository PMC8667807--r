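# ringcharge

Subunit composition is the master variable of ionotropic glutamate receptor
(AMPA/NMDA) physiology: whether a synapse's receptors pass Na⁺, Ca²⁺ or both
is decided by which of the GluN1, GluN2A–D, GluN3A/B or GluA1–4 subunits make
up the tetramer — most famously by Q/R editing of GluA2, which abolishes Ca²⁺
permeability of AMPARs. `ringcharge` is for neurophysiologists and channel
modellers who want those selectivity predictions computed, audited and
extended (point mutants, hypothetical n-mers, anions) rather than looked up.

## The model

Each subunit contributes the pore-lining residue of its M2 re-entrant loop to
the selectivity filter. Polar uncharged side chains (N, Q, S, T) present a
partial negative charge, treated as a full elementary charge; all other
residues (including the arginine introduced by Q/R editing) contribute
nothing. A tetramer therefore carries an integer **ring charge**

    r_q = Σ contribution(filter residue of subunit s),   r_q ≤ 0.

An ion of charge `q_i` entering a pore whose resident carries charge `q_r`
(0 when empty) permeates iff both binary gates pass:

    A(r_q, q_i)        = 1  iff  |r_q + q_i| > 0          (charge attractivity)
    B(r_q, q_i, q_r)   = 1  iff  q_i + |r_q + q_r| > q_r  (inward drive)
    permeable          = A × B

Channel-level selectivity follows from chaining displacement events: states
are `EMPTY` plus one occupied state per ambient ion, with an edge `s → i`
whenever ion `i` permeates from state `s`. The terminal strongly connected
classes reachable from `EMPTY` define steady-state selectivity — e.g. at
`r_q = −3` the Ca²⁺-occupied state is absorbing, so the channel ends up
Ca²⁺-selective even though Na⁺ conducts initially.

## Worked example

```r
library(ringcharge)
predict_report("GluN1/GluN2B/GluN3A/GluN2B")   # a triheteromeric NMDAR
```

```
== ringcharge prediction ==
composition: GluN1/GluN2B/GluN3A/GluN2B
ring charge r_q = -3

displacement matrix (entering x resident):
 entering resident A residual B permeable
      Na+    EMPTY 1        3 1         1
      Na+      Na+ 1        2 1         1
      Na+     Ca2+ 1        1 0         0
     Ca2+    EMPTY 1        3 1         1
     Ca2+      Na+ 1        2 1         1
     Ca2+     Ca2+ 1        1 1         1

selectivity classes:
  ion unconditional steady_state conditional
  Na+             0            0           1
 Ca2+             1            1           0
```

Reading: the three GluN2-type asparagines plus one GluN1 asparagine minus the
GluN3A glycine give `r_q = −3`. Na⁺ is attracted (`A = 1`) everywhere but
cannot displace a resident Ca²⁺ (`1 + |−3 + 2| = 2 ≯ 2`), so once Ca²⁺ takes
the pore it keeps it: Na⁺ is only conditionally permeable, Ca²⁺ is permeable
in steady state — the receptor selects Ca²⁺ over Na⁺.

Other entry points: `ring_charge()`, `working_table()` (the cell-by-cell
audit of a verdict), `selectivity_profile(c(-4, 0))` (permeability vs ring
charge), `anion_scan()` (Cl⁻ occlusion intervals and threshold),
`mutate_subunit("GluA2", 605, "R")`, `anchor_filter_residue()` (locate the
filter residue in your own sequence by global alignment), and a CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ringcharge.R",package="ringcharge"))')" \
    predict --composition GluN1/GluN3A/GluN1/GluN3A --ions Na,Ca
```

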