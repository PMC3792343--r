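# loxtron

Design and simulation toolkit for bacterial genome editing with
**targetron-delivered Cre-lox sites**: mobile group II introns ("targetrons")
retargeted to chosen loci carry 34-nt lox sites into the genome, and a single
round of Cre expression then executes large-scale deletions, inversions,
cassette-exchange insertions, or one-step cut-and-paste translocations —
no selectable marker in the genome, efficiency near 100% for two-site
operations.

`loxtron` is for people planning such edits and for anyone modelling
site-specific recombination outcomes. It provides:

- **Lox-site algebra** — sites decomposed as `left arm (13 nt) | linker
  (8 nt) | right arm (13 nt)`. Linker classes (P, 511, FAS, m2, 2272, N) are
  mutually orthogonal; Cre recombination exchanges arms across the linker,
  `(aL·l·aR) × (bL·l·bR) → (aL·l·bR) + (bL·l·aR)`, so a left-arm mutant
  (lox71) times a right-arm mutant (lox66) yields the Cre-inert double
  mutant lox72 plus a wild-type site — the irreversibility ratchet behind
  every design.
- **Annotated molecules** and intron insertion with full feature
  bookkeeping, FASTA/GenBank IO.
- **A Cre reaction simulator** (`cre_step`, `cre_closure`) that enumerates
  excisions, inversions and integrations over a multi-molecule state and
  reports the terminal outcomes of the transition graph, plus **host
  homologous recombination** between intron scaffolds (direct-repeat
  collapse, adjacent inverted-repeat removal, reversible inversion) and a
  qualitative design classifier (`classify_design`).
- **Verification planning** — locus-flanking primer design, exact in-silico
  PCR (circular-aware), and the 3/4/6-assay diagnostic schemes for
  deletion/inversion/cut-and-paste with predicted W/U/I band signatures.
- **Cargo-insert design and RNA flexibility scoring** (Nussinov base-pair
  maximization with GU pairs; GAGAG-flanked flexible inserts).
- **Intron retargeting** — naming grammar, candidate-site enumeration by
  base-pairing templates, retargeting fragments and primer sets.
- **Growth-curve doubling times** — the windowed-R² estimator: log2(OD600)
  vs time, 7-point per-point R², replicate-averaged, longest run ≥ 0.99 as
  the linear region, doubling time = 1/slope per replicate, mean ± SE.
- **Seeded synthetic fixtures** for genomes and plate-reader curves.

## Worked example: plan, simulate and verify a deletion

```r
library(loxtron)

# synthetic 24-kb circular genome with two named loci
fx <- make_genome(fixture_spec(seed = 7, genome_length = 24000,
                               loci = c("A", "lacZ")))

# lox71 upstream, lox66 downstream, same orientation: a one-way deletion
plan <- edit_plan("deletion", list(list(
  locus_up   = plan_site("A",    "lox71", "forward", "EcI5", "s"),
  locus_down = plan_site("lacZ", "lox66", "forward", "EcI5", "s"))))

u   <- apply_plan(plan, fx$molecule)   # uninduced strain: introns in place
rep <- cre_closure(u)                  # all Cre-reachable outcomes
rep
#> <outcome report> 2 state(s) explored, 1 terminal outcome(s)
#>   reversible: FALSE
#>   inverted repeat generated: FALSE
rep$terminal_states[[1]]
#> <system state> 2 molecule(s), 1 event(s) applied
#>   genome: 13056 bp circular, 1 lox
#>   genome.c01: 13056 bp circular, 1 lox
```

One Cre event excises the 10-kb A–lacZ region as a circle; the chromosome
keeps a single 34-nt lox72 scar (the one lox on `genome` is inactive), so
nothing can revert — `reversible: FALSE`.

```r
ap <- design_assays(plan, fx$molecule)
ap$assays$name
#> [1] "Au/Ad" "Lu/Ld" "Au/Ld"
sig <- predict_signature(ap, list(W = fx$molecule, U = u,
                                  I = loxtron:::induced_state(plan, fx$molecule)))
sig
#>   assay        role state n_bands sizes
#> 1 Au/Ad site_bridge     W       1   320
#> 2 Lu/Ld site_bridge     W       1   320
#> 3 Au/Ld    junction     W       0
#> 4 Au/Ad site_bridge     U       1  1376
#> 5 Lu/Ld site_bridge     U       1  1376
#> 6 Au/Ld    junction     U       0
#> 7 Au/Ad site_bridge     I       0
#> 8 Lu/Ld site_bridge     I       0
#> 9 Au/Ld    junction     I       1  1376
```

The three PCRs give the classic diagnostic signature: the two insertion-site
bridges are small (320 bp) in the wild type, about 1 kb larger (1376 bp)
once the introns are in, and disappear after induction, while the junction
assay `Au/Ld` lights up only in the induced strain.

A command-line interface wraps the same functions
(`exec/loxtron <fixtures|simulate|verify|growth|design-insert|retarget>`),
reading edit plans from YAML and writing GenBank/TSV/JSON reports.

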