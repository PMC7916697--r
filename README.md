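# tccselect

Screening support for selective T-type calcium channel (TCC, Cav3.x) blockers.

Most phenylalkylamine (PAA) blockers of T-type channels — mibefradil being
the classic case — also inhibit L-type channels (LCC, Cav1.x), which limits
their therapeutic use. The structural pivot between the two families sits in
the pore: L-type channels coordinate Ca²⁺ with a ring of four glutamates
(EEEE) and bind PAAs near domains III–IV, while every T-type channel carries
a lysine (K³ᵖ⁴⁹) immediately adjacent to the domain-III filter aspartate
(D³ᵖ⁵⁰) of its EEDD ring. The positive lysine interferes with the
Ca²⁺–aspartate attraction, shifting the preferred Ca²⁺ — and hence PAA —
binding region to domains I and IV. A compound predicted to bind domains
I/IV of the T-type models but not domains III/IV of the L-type model is a
selective-blocker candidate.

`tccselect` implements the desk-side parts of that screening strategy:

* **Coulomb interference model.** For formal charges q(Ca²⁺) = +2,
  q(Asp) = −1, q(Lys) = +1 at separations in Å,

  F(Ca,D) = kₑ·q_Ca·q_D·e²/a²,  F(Ca,K) = kₑ·q_Ca·q_K·e²/r²·cos θ,

  with the Ca–Lys distance solved from the triangle
  r = a·cos θ ± √(b² − a²·sin²θ) (the sign chosen by the angle φ at the
  lysine vertex), and the net axial force F(Ca,D,K) = F(Ca,D) − F(Ca,K).
  Even in the minimal-interference configuration (lysine collinear on the
  far side, r = a + b) the lysine removes >28 % of the attraction; closer
  placements reduce it further or reverse it.
* **Sequence signatures.** A parser for the KcsA-aligned residue labels
  (`3p49` = domain III, P-loop, position 49), an S5/P-loop/S6 alignment
  container, and the lysine-signature classifier (TCC ⇔ K at 3p49 next to
  D/E at 3p50).
* **Docking triage.** ΔG → K_d conversion (K_d = exp(ΔG/RT), T = 310 K),
  the domain-based selectivity rule over docking tables, and candidate
  ranking against reference blockers.
* **Drug-likeness.** Crippen logP, Ertl–Schuffenhauer synthetic
  accessibility and QED via RDKit, plus the strict
  lower-logP/higher-QED filter against reference blockers.
* **Synthetic cohorts.** A seeded generator of docking + property tables
  with known ground truth for validating the whole pipeline.

Bundled plain-text datasets: the Cav1.2/Cav3.1 pore-domain alignment
(`table4Fixture()`), a 24-row PAA docking summary (`table2Fixture()`) and a
17-compound property table (`table3Fixture()`).

## Worked example

```r
library(tccselect)

## How much attraction does the domain-III lysine remove at minimum?
minimalInterference(a = 4.3, b = 3.8)
#> $fAttract          2.489389e-09   # N, Ca2+ <- D3p50
#> $fRepel            7.015516e-10   # N, axial lysine repulsion at r = 8.1 A
#> $r                 8.1
#> $reductionPercent  28.18168       # >28% even in the best case

## Which family is Cav3.1?
classifyChannel(table4Fixture(), "a1G")
#> a1G: TCC (3p49 = K, 3p50 = D, filter motif EEDD)

## Selectivity triage of the bundled docking table
classifySelectivity(table2Fixture())[, c("compound", "category", "best_tcc_dg")]
#>      compound      category best_tcc_dg
#>    Mibefradil  dual_blocker        -7.4
#>   NNC 55-0395  dual_blocker        -6.6
#>   NNC 55-0396 TCC_selective        -8.1
#>   NNC 55-0397  dual_blocker        -7.5
#>    RO 40-5966  dual_blocker        -7.4
#>     SKF-96365 TCC_selective        -5.6

## Binding free energy to dissociation constant
deltaGToKd(-6.8)$kd_molar
#> 1.596587e-05     # molar, thermodynamic convention

## Drug-likeness filter against the four reference blockers
p <- table3Fixture()
flt <- referenceFilter(p[p$role == "candidate", ], p[p$role == "reference", ])
flt[flt$id == "TC 7", c("logp", "qed", "pass")]
#>   logp    qed  pass
#> 3.6902 0.6338  TRUE   # lower logP and higher QED than every blocker
```

A compound is `TCC_selective` when some T-type receptor (a1G/a1H/a1I)
reports a binding free energy with binding domain I or IV while the L-type
receptor a1C reports none in domains III/IV; compounds hitting both are
`dual_blocker`s. NNC 55-0396 is the strongest selective hit (−8.1 kcal/mol
on a1G, K_d ≈ 2×10⁻⁶ M); mibefradil's −6.4 kcal/mol on a1C domain IV marks
it dual, matching its known cross-inhibition.

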