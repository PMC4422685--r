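# apehkit

Domain-resolved structural and expression analysis of two-domain
acylpeptide hydrolases (APEH) and similar proteins, in R.

APEH (acylpeptide hydrolase / oxidised-protein hydrolase) is a serine
peptidase of the prolyl-oligopeptidase family built from two domains: an
N-terminal β-propeller that gates substrate access and a C-terminal α/β
catalytic domain carrying a Ser–Asp–His triad, joined by a ~10-residue
linker. Fish genomes carry two isoform clusters with strikingly different
substrate behaviour, and a useful working hypothesis is electrostatic: the
net charges of the two domains decide whether they attract (closed,
exo-peptidase-like behaviour) or repel (open, able to take bulky oxidised
substrates). `apehkit` packages the analyses needed to examine that
hypothesis on any two-domain structure or sequence:

- **Charge profiling** — per-domain counts of acidic (D+E) and basic
  (H+K+R) residues and net charges, `net = #(H,K,R) − #(D,E)`, plus
  sequence-derived average molecular masses.
- **Interaction detection** — salt bridges (any Asp/Glu carboxylate O
  within 4.0 Å of a Lys/Arg/His side-chain N, residue-pair granularity)
  and hydrogen bonds (heavy-atom donor–acceptor tables, d(D···A) ≤ 3.5 Å
  with an ideal-amide-H angle test; a stricter H-resolved preset is
  available), classified intra-/inter-domain against a domain partition.
- **Catalytic-site environment** — side-chain atoms within 3 Å of the
  triad, with per-atom charge classes and a
  negative/positive/balanced summary.
- **Hinge opening** — rigid rotation of everything C-terminal to a linker
  backbone bond (N–Cα or Cα–C) by chosen angles, with opening metrics
  (inter-domain centroid distance, minimum inter-domain distance,
  site-exposure proxy, clash count) and a heuristic opening-propensity
  score: the product of the two domain net charges (positive = repulsion =
  open-prone).
- **Expression** — efficiency-corrected relative expression from qPCR Ct
  tables, `R = (1+e_target)^ΔCt_target / (1+e_ref)^ΔCt_ref` with ΔCt =
  control − sample, plus per-tissue fold-ratio tables for isoform pairs.
- **Synthetic data** — ideal-geometry peptide builder, a designed
  two-domain toy with known interaction ground truth, and simulated Ct
  tables from known fold changes, so every stage is testable offline.

## Worked example

```r
library(apehkit)

# a designed two-domain toy: two helical domains, ten-residue linker,
# two inter-domain salt bridges at 3.2 A and one H-bond at 2.9 A
toy <- make_two_domain_toy(n_salt_bridges = 2, n_hbonds = 1, seed = 1)

sb <- classify_interdomain(find_salt_bridges(toy$structure), toy$partition)
interaction_counts(sb)
#>   total intra-N intra-C   inter  linker
#>       2       0       0       2       0

opening_series(toy$structure, toy$hinge, c(20, 40, 60, 80),
               toy$partition, toy$triad)$metrics
#>   angle centroid_distance min_interdomain_distance exposure_count clash_count
#> 1    20          17.17707                 4.707290              0           0
#> 2    40          22.44933                 7.186239              0           0
#> 3    60          27.41053                 9.753677              0           0
#> 4    80          31.73815                12.140401              0           0
```

The two designed bridges are recovered exactly, and rotating the
C-terminal domain about the linker N–Cα bond opens the structure
monotonically (the unrotated toy has centroid distance 12.24 Å and 15
N-domain atoms crowding the catalytic site; by 80° the site is fully
exposed).

Charge-based opening propensity from the published per-domain net charges
of the four Antarctic isoforms:

```r
ref <- apeh_domain_charges()
wide <- data.frame(protein = unique(ref$protein),
                   nter_net = ref$net[ref$region == "N-ter"],
                   cter_net = ref$net[ref$region == "C-ter"])
opening_propensity_score(wide)
#>     protein nter_net cter_net score total_net rank
#> 1 APEH-1_Ch        1       -2    -2        -1    1
#> 2 APEH-1_Tb       -6       -3    18        -9    2
#> 3 APEH-2_Ch        7        7    49        14    3
#> 4 APEH-2_Tb        9        7    63        16    4
```

APEH-1_Ch is the only isoform whose domains attract (score −2): it ranks
least open-prone, consistent with its poor activity on bulky oxidised
substrates.

Expression, with the packaged published primer efficiencies:

```r
eff <- apeh_primer_efficiencies()
pfaffl_ratio(e_target = 1.102, e_ref = 0.959, dct_target = 2, dct_ref = 2)
#> [1] 1.151321
```

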