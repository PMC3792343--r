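---
title: "Designing and simulating targetron-delivered Cre-lox genome edits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating targetron-delivered Cre-lox genome edits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxtron)
```

## The editing system being modelled

Retargetable mobile group II introns ("targetrons") insert into a chosen DNA
site by base-pairing between the intron RNA and the target, at efficiencies
high enough that no selectable marker is needed. Placing a lox site in the
intron's cargo position (domain IV, where the intron-encoded protein sits in
the wild-type element) turns the targetron into a delivery vehicle for Cre
recombination targets. Once two or three lox sites are positioned, a single
round of Cre expression executes a large-scale deletion, inversion,
cassette-exchange insertion, or one-step cut-and-paste translocation.
`loxtron` models this design space in silico: the algebra of the sites, the
reachable set of Cre products, the side reactions the host's own homologous
recombination contributes, the diagnostic PCRs that verify each edit, and
the growth-curve fitness readout.

## Lox-site algebra

A lox site is 34 nt: two 13-nt arms flanking an asymmetric 8-nt linker. The
linker's sequence class (P, 511, FAS, m2, 2272, N) determines which sites
can recombine — distinct classes are treated as fully mutually incompatible
by default, which is how multi-site designs avoid cross-reaction; a custom
compatibility matrix can be supplied because compatibility is a property of
linker pairs, not something computed from an alignment. Arm mutations tune
Cre binding: a left-arm mutant (lox71-type) recombining with a right-arm
mutant (lox66-type) produces one double-mutant site (lox72-type) that Cre no
longer recognizes, plus one wild-type site. This is the one-way ratchet every
irreversible design in the package relies on.

Sites are stored in the *linker-forward frame* — arms and linker always read
in the direction in which the linker matches its catalogue class — with the
strand carried as an orientation flag. The crossover is then a frame-free arm
exchange: `recombine(a, b)` returns `a$left + linker + b$right` and
`b$left + linker + a$right`, with arm-mutation states travelling with their
arms. The shipped catalogue (`inst/extdata/lox_catalog.tsv`) uses the
canonical published sequences for these sites; every operation and test works
on the decomposed representation, so the exact strings are configuration,
not load-bearing constants.

## Molecules, introns and coordinates

Molecules are circular or linear annotated sequences with 0-based half-open
feature intervals on the reference strand. One internal convention avoids
off-by-one drift; the 1-based gene-relative positions used in intron names
(`EcI5.LacZ.1806s`) exist only in the naming layer. Features never wrap the
origin of a circle: operations rotate the representation instead, and intron
features that a rotation or splice cuts are clipped into remnants whose
payload records which scaffold interval is still present. That bookkeeping
is what lets the simulator reason about homology between intron remnants
after recombination has cut through them.

Intron scaffolds default to deterministic synthetic stand-ins of 1 kb per
type (`Ll.LtrB`, `EcI5`), sized to reproduce the roughly 1-kb growth of
verification amplicons after intron insertion; real scaffolds can be loaded
from GenBank. The two synthetic types share no designed homology, matching
the use of non-homologous introns to suppress host recombination. Homology
between two intron (remnant) features is decided by identical type plus a
minimum shared scaffold run (default 200 nt, configurable).

## The Cre transition system

`cre_step()` enumerates one successor per unordered pair of active,
linker-compatible sites: intramolecular same-orientation pairs excise the
intervening region as a circle (the circle is retained in the state — it
carries an active site and can re-integrate, which is precisely the
cut-and-paste mechanism); opposite-orientation pairs invert the segment;
pairs on two circles fuse them. `cre_closure()` explores the reachable state
space breadth-first, deduplicating states by a canonical key that is
invariant to rotation and strand choice of each circular molecule, with a
configurable bound (default 10,000 states) and an explicit truncation error
beyond it.

Terminal outcomes are defined through the structure of the transition graph:
the entry states of its terminal strongly connected components. Reversible
events (wild-type by wild-type exchanges) generate cycles inside a
component; formation of a lox72-type site is what creates an irreversible
exit. This definition reproduces the expected behaviour of all four edit
types, including the two-step cassette exchange (integration forming one
lox72, then backbone excision forming the second) where a naive
"stop at the first lox72" rule would terminate half-way. For three-site
cut-and-paste designs the enumeration is deliberately honest: besides the
intended translocation, the two single-arm-mutant sites can always react
directly with each other and lock a spurious product. The simulator reports
both terminal outcomes — consistent with cut-and-paste colony screens being
positive in most but not all colonies, unlike the near-100% two-site
operations — and downstream consumers select the operation-consistent
terminal when they need a single induced state.

## Host homologous recombination

The host's recombination machinery acts on repeated intron scaffolds
independently of Cre. `host_recombination()` emits, for each homologous
pair: a collapse for direct repeats (one repeat copy plus the intervening
sequence deleted, crossover placed at the start of the shared scaffold
interval), outright removal for *adjacent* inverted repeats (gap at most
100 nt — the recombinant lox scar), and a reversible inversion for separated
inverted repeats (crossover at the midpoint of the shared interval). Removal
of an adjacent inverted repeat deletes the lox sites entirely and leaves a
scar of 40 nt of scaffold remnant by default — configurable, since the
biology is characterized only as reducing the scar from hundreds to tens of
base pairs. The removal pass runs as deterministic post-processing after the
Cre closure because the cell applies it subsequently, not interleaved.

`classify_design()` folds these pieces into the qualitative outcome columns
used to summarize rearrangement strains. *Inverted repeat generated* is
scanned on the terminal states: an adjacent homologous intron-remnant pair
in inverted orientation. Adjacency matters — introns inserted in opposite
orientations form far-apart inverted copies before Cre ever acts, and those
are not "generated" by the recombination. *Recombination in the absence of
Cre* is a structural rule on the uninduced state: homologous introns must be
present in an orientation whose recombination product reproduces the
designed operation (direct repeats mimic a deletion, inverted repeats an
inversion); for cut-and-paste designs an inverted homologous pair yields
only the intermediate inversion, reported as the partial level. The shipped
rearrangement panel (`rearrangement_panel()`) exercises all twelve
representative designs and the classifier reproduces both columns for every
row.

## Cassette-exchange geometry

Which exchange junction inherits the double-mutant site depends on the
relative order and orientation of the sites, not only on their identities:
the excision junction retained by the chromosome combines the upstream
site's left arm with the downstream site's right arm. The default
arrangement — genome `loxm2/71` upstream of `lox66`, delivery cassette
ordered `loxm2/66`, cargo, `lox71`, backbone — is the one whose final
chromosome carries the cargo between a lox72 and an m2 double mutant, with
both wild-type products leaving on the curable backbone circle. Other
orderings of the same four sites leave active sites flanking the cargo;
`validate_plan()` checks the arm pattern but the geometry itself is encoded
in `apply_plan()`'s construction.

## Verification planning

Primer design is deliberately minimal: the leftmost unique 20-mer within a
300-nt window flanking each insertion point, uniqueness checked genome-wide
by exact match on both strands. No thermodynamic screening is attempted.
In-silico PCR is exact-match annealing of convergent primers up to a 5-kb
product cap, searched across the origin of circular molecules with products
capped at the molecule length. Assay sets follow the diagnostic scheme:
three assays for a deletion (two insertion-site bridges plus the junction),
four for an inversion (the bridges plus the two new ends), six for a
cut-and-paste (three bridges, the cut junction, two paste boundaries; the
paste-boundary primer pairing is resolved against the simulated induced
state because it depends on the insertion orientation). Expected signatures
follow the wild-type / uninduced / induced logic: site bridges small in W,
about 1 kb larger in U, absent in I; junction-type assays present only in I,
with the deletion junction shrinking by more than a scaffold length when an
adjacent inverted repeat has been removed by the host.

## Cargo inserts and structural flexibility

Cargo inserts place one or two lox sites between MluI cloning ends, two-site
payloads separated by a PmeI site plus a short linker. Because palindromic
lox arms fold into tight RNA hairpins that can disrupt intron folding,
flexible variants add `GAGAG` at both ends of the payload. Structure is
judged with a base-pair maximization fold (`fold_rna()`): Nussinov dynamic
programming with Watson-Crick plus GU pairs, minimum hairpin loop 3 nt, and
a deterministic traceback preferring the pairing partner at the smallest 5'
index. A thermodynamic model is intentionally not used — the structures are
consumed qualitatively (presence and size of non-pairing regions), and
externally computed dot-bracket strings can be supplied instead via
`parse_dotbracket()`.

Scoring strips the MluI ends (a perfect reverse-complement pair that would
always seal the stem) and ignores lone, unstacked pairs, which pure
maximization otherwise scatters across the GAGAG flanks; what remains is the
helix content. An insert is classed flexible when at least 2 of the 5
positions at each end — the base of the stem — are unpaired; the threshold
is configurable because the underlying two-class distinction is qualitative.
Under these defaults the shipped catalogue behaves as designed: GAGAG-flanked
versions never score below their rigid counterparts. The synthetic payloads
are stand-ins, so per-insert class labels are not asserted beyond that
monotonicity.

## Retargeting

Intron names parse and format through the `TYPE.GENE.POSITIONs|a[.CARGO]`
grammar. Candidate insertion sites are enumerated by scanning every position
on both strands for windows satisfying a template's hard base constraints;
the published efficiency-scoring algorithms are prior work used as a black
box, so the template exposes a scorer plug-in instead of re-implementing
them. Element ranges (EBS2, EBS1, delta) default to editable per-type
configuration. `build_fragment()` rewrites the scaffold elements to the
reverse complement of their target ranges, labels the fragment ends with the
cloning sites used per type (HindIII/BsrGI for Ll.LtrB, AvaII/XbaI for
EcI5), and emits the four-primer or two-PCR primer sets; fragment assembly
is modelled as sequence concatenation at the declared junctions.

## Doubling times

Plate-reader curves are analysed exactly as the fitness measurements
prescribe: log2(OD600) against time in minutes; each interior point gets the
R-squared of the regression through its 7-point window (the point plus three
before and after); the per-point values are averaged across the three
replicates; the longest contiguous stretch with averaged R-squared at least
0.99 is the linear region (ties resolve to the earliest stretch;
zero-variance windows are assigned 0 and thus excluded). Each replicate's
least-squares slope over the common window has units of doublings per
minute, so the doubling time is its reciprocal — the reciprocal is taken
deliberately, as a slope itself cannot be minutes per doubling — and the
result is the replicate mean with its standard error.

```{r growth}
spec <- growth_spec(seed = 1, od0 = 0.001, lag_min = 60,
                    doubling_time = 33.25, stationary_od = 1,
                    interval_s = 560, noise = 0.01, replicates = 3)
doubling_time(make_growth_curves(spec))
```

## Synthetic fixtures and what they do not show

All inputs are generated: uniform-random ATGC genomes with evenly spaced
gene loci, each preceded by a unique 25-nt barcode guaranteeing primer
placement; growth curves with three phases (flat lag, exponential at the
specified doubling time, saturation at the stationary cap) and
multiplicative log-normal noise, per-replicate streams derived from one
master seed. Generators are pure functions of (spec, seed) and leave the
caller's RNG state untouched. Defaults mirror the measurement setup being
emulated: starting OD 0.001, 560-s sampling, 1% noise, three replicates.

Real data differ in ways the fixtures deliberately ignore: genomes have
biased composition and repeated elements (so unique primers are not
guaranteed within 300 nt), real growth curves have smooth phase transitions
and autocorrelated residuals rather than a sharp lag corner and independent
noise, and real intron efficiency depends on target-site sequence in ways
the hard-constraint templates do not capture. Passing tests therefore show
the algorithms are implemented as specified, not that the biology will
cooperate at any particular locus.

## Problem sizes and numerical choices

The test suite runs panel classifications on 16-24 kb genomes with 8-kb
locus spacing (the simulated spans scale down the chromosomal distances; the
qualitative outcomes depend only on geometry, not size), oracle-equivalence
checks on molecules up to 2 kb with up to 3 sites against a brute-force
string-splicing enumerator, in-silico PCR against a substring-scan oracle up
to 10 kb, folds against an exhaustive recursion up to 60 nt, and doubling
time recovery over 100 seeded simulations (true values 20-40 min, 1-3%
noise), where the median relative error stays under 2%. Deterministic
tie-breaks throughout: earliest linear-region run, smallest-5'-index fold
traceback, lexicographically least rotation as the canonical frame of a
circle. Degenerate inputs raise classed conditions
(`loxtron_length_error`, `loxtron_design_error`,
`loxtron_no_linear_region_error`, `loxtron_state_bound_error`, ...) rather
than guessing.
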