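---
title: "The loopassembly model: recursive Type IIS assembly in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The loopassembly model: recursive Type IIS assembly in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopassembly)
```

# The reaction model

## Cut geometry

A Type IIS enzyme is modelled as `(recognition, spacer, overhang_len)`.
For a recognition site on the plus strand at 0-based position $s$ the top
(Watson) strand is cut at boundary $s + |rec| + spacer$ and the bottom
(Crick) strand `overhang_len` further, leaving a 5′ overhang whose
top-strand text is the interval between the two cuts. A minus-strand site
mirrors this upstream. The shipped enzymes are BsaI (`GGTCTC`, spacer 1,
4-nt overhang; odd assembly levels) and SapI (`GCTCTTC`, spacer 1, 3-nt;
even levels), but the engine is enzyme-agnostic — the test suite uses the
same code paths with toy geometries.

Both overhangs of a fragment are stored as the *top-strand text of the
duplex they form on ligation*, which reduces sticky-end compatibility to
string equality and makes orientation flips purely mechanical
(`flip_fragment`). A fragment's core runs between successive Watson cuts
and includes its left overhang bases while excluding its right ones; this
convention makes circular digestion exactly length-conserving
(Σ core = parent length), which the suite asserts on 1,000 random circular
molecules.

## The end-state abstraction

The thermocycled digestion–ligation equilibrium is not simulated
kinetically. Instead the package adopts the standard Golden Gate end-state
argument: any circular product still carrying a recognition site of the
reaction enzyme is re-cut on the next 37 °C excursion, so only site-free
circles are stable end products. `one_pot_assemble` therefore (i) digests
all inputs, (ii) enumerates every sticky-end-closed circular product
(bounded copy number, deduplicated up to rotation and reflection via a
Booth least-rotation canonical form), and (iii) classifies: *intended*
(backbone + exactly one release fragment per insert, dropout absent),
*parental* (re-ligation reconstituting an input plasmid — the lacZ+ blue
colony class, reported but never counted as product), *misassembly* (any
other stable circle). Re-running the same enzyme on the intended product
raises `uncut circular` — the scar-free property — while the opposite
enzyme releases the composite: the Loop recursion invariant, tested across
all four receiver positions and both parities.

Ligation enumeration is exhaustive depth-first chain extension seeded from
every fragment in both orientations, with a configurable chain cap that
aborts with the list of duplicated overhangs (the practical cause of
combinatorial blow-ups). For pools of ≤ 6 fragments the suite checks the
output set against an independent brute force over all subsets ×
permutations × orientation vectors.

# The grammar layer

## Overhang alphabets

The even (SapI) alphabet is fixed: α `ATG`, β `GCA`, γ `TAC`, ε `CAG`,
ω `GGT`. The odd (BsaI) alphabet follows the community common syntax but
its sequences are deliberately *configuration*, not contract: defaults
`A GGAG, B TACT, C AATG, D AGGT, E GCTT, F CGCT` ship in
`default_overhang_table()` and every test derives its expectations from the
active table, so replacing the defaults (e.g. to match a local standard)
cannot silently break correctness claims. Both alphabets must pass
`fidelity_check` (no duplicates, no self-complementary overhangs, no
complement collisions) — the constructor enforces this.

The default D code was chosen to satisfy the CDS junction rule: a CDS part
ending on D carries no stop codon and ends in `GC`, so the junction
completes an alanine codon (`GC·n`) and the overhang's central `GG` begins
a glycine codon; hence D must match `nGGn` (`check_d_rule`). The frame
convention is `ATG` (supplied by the C overhang) followed directly by the
insert.

## Receivers and the recursion

A receiver cassette is
`UNS1 – [release site →] – accept_left – [← assembly site] – lacZ –
[assembly site →] – accept_right – [← release site] – UNSX`.
The assembly-enzyme sites point away from the cargo, so both recognitions
leave with the dropout and the backbone fragment is clean; the
release-enzyme sites point inward, so after assembly the product carries
exactly two release sites whose cuts excise the cargo *with* the next
level's code overhangs. Odd receivers accept `(A, F)` and release
`(σ_pos, σ_pos+1)` over the α…ω chain; even receivers accept `(α, ω)` and
release over a five-term odd-letter chain. That chain's interior codes are
not fixed by the scheme itself; the defaults reuse `A, B, C, E, F` —
mirroring the junctions of the canonical L1 part chain — which is safe
because interior odd codes are consumed as scars at the previous odd level
and carry no recognition sites. It, the UNS sequences and the entry
overhangs are all config-replaceable (`load_overhang_config`).

Marker alternation is structural: odd receivers are kanamycin, even ones
spectinomycin (pCA, pCO) or chloramphenicol (pSB, pAN), and the planner
rejects any edge where parent and child select on the same antibiotic.

## L0 entry

One universal SapI entry vector cannot itself supply part-specific BsaI
codes (the SapI cut would have to land inside the 4-nt code, which its
geometry cannot reach past its own recognition site). The package therefore
models the entry cassette — standing in for the domesticated PCR product —
as carrying the complete BsaI release flanks
(`GGTCTC·N·five_code … three_code·N·GAGACC`) between fixed 3-nt entry
overhangs exposed by the vector. This reproduces the observable contract
exactly: entry is SapI-mediated, the resulting plasmid is SapI-free, and
BsaI releases the insert with the declared codes (asserted at construction
time for every part built).

## Domestication

`domesticate` destroys each internal site with exactly one substitution.
Inside a declared CDS interval the edit must be synonymous at Hamming
distance 1 (codon alternatives tried left-to-right in lexicographic order;
an inescapable codon is a hard error naming it); outside, the last base of
the recognition sequence *on its own strand* — its most degenerate
position — is mutated to its transition base, a single deterministic
choice. Because edits can create new sites, scanning iterates to a fixpoint
bounded at 10 passes. Translation preservation is property-tested on
randomized planted-site ORFs.

# The planner

Designs are trees (leaves: L0 part references; internal nodes: level, kit,
receiver position, ordered children) serialisable as JSON. Validation
enforces level alternation, slot/position agreement, marker alternation and
chain completeness; nodes of level ≥ 2 must have full four-child chains —
partial chains are rejected rather than auto-filled with spacer parts,
because inventing parts the user never declared would change the construct.
Level 4 is receiver-free by default (linear product plus the
monomer/dimer/trimer concatemer ladder); a receiver-borne level-4 mode
exists but warns about direct-repeat instability, the observed failure mode
of such plasmids in vivo. Simulation is bottom-up `one_pot_assemble` at
every node with memoisation of identical (design, receiver) subtrees; each
level-1 product gains a `TU:` feature over its cargo, and features
propagate through every subsequent digestion/ligation, so the census of the
root product equals the census of the plan — an identity the acceptance
suite asserts rather than assumes.

Recipes use the measured reaction format: 15 fmol per part, 7.5 fmol
receiver, 5 µl DNA mix + 5 µl parity-specific master mix, 25 regular cycles
(3 min 37 °C / 4 min 16 °C) with short-cycle, 50-cycle and 2× enzyme
variants. fmol→ng conversion uses 650 g·mol⁻¹·bp⁻¹ (exposed as an
argument, since the protocol states targets in fmol but benches measure
ng/µl).

# Verification readouts and metrics

Digest profiles are band-length lists (bp), scored against expectations by
*exact* bipartite matching within a per-band tolerance (default 100 bp —
agarose-gel resolution); greedy pairing would wrongly fail cases like
`{100, 90}` vs `{95, 86}` at ±10. Gel mobility is not modelled: the scheme
scores patterns, not migration distances. In-silico PCR is exact-match by
default (verification primers are exact by design; a mismatch budget
exists but 3′-end rules are not modelled) and wrap-aware, with the UNS1/
UNSX pair as the standard primers — every receiver-borne product yields
exactly one amplicon. The efficiency calculator implements
`100 × fluorescent / (fluorescent + white)` with blue (parental) colonies
excluded, and productivity multiplies white-colony counts by the plated
fraction factor, default 30 (10 µl plated of 300 µl recovery) but exposed
as a parameter because other experiments plate differently.

# The synthetic fixture generator

`generate_fixtures(seed)` builds four kits × eight receivers on random
site-free backbones (2–4 kb, scrub-sampled), the entry vector, and the
benchmark part library, bit-reproducibly from the seed. Choices a real
dataset would have pinned down:

* **Part lengths** are drawn so L1 products land around 3–4 kb and L3
  composites in the tens of kb — the reported size bands, qualitatively.
  Exact sizes are *not* test expectations; the real vectors live in public
  accessions this package does not download.
* **N7 tag placement**: the census arithmetic of the 64-TU construct
  (32 N7 tags; 31 untagged mRuby3 CDSs) forces N7 into the mTurquoise2 and
  Venus TUs and none into mRuby3; the mRuby3 TU uses a `DE_3xSTOP` filler
  part instead. This is the unique assignment consistent with the printed
  totals and is documented as derived, not copied.
* **UNS1/UNSX and backbone sequences are synthetic**; grammar, site
  placement and feature labels are faithful, nucleotide content is not.

A green test therefore establishes the combinatorial and grammatical
correctness of the scheme — chains, overhangs, site loss, census, recipe
arithmetic — but says nothing about ligase kinetics, transformation
efficiency, or in vivo stability, none of which are modelled (no
partial-digest, methylation-sensitivity or band-intensity modelling
either).

# Numerical and degenerate-input choices

* Product identity: circular molecules compare by the lexicographically
  least rotation of sequence and reverse complement (Booth's algorithm,
  O(n)); linear products up to reversal. Enumeration output is sorted by
  (length, canonical sequence) — a total, deterministic order.
* `N` is accepted in sequences but never matches inside a recognition site
  and never base-pairs in an overhang (conservative site calling).
* Blunt–blunt ligation is excluded; linear termini of uncut linear
  molecules are blunt (`""` overhangs).
* An uncut circular molecule is an error class of its own
  (`loop_uncut_circular`) — distinct from "no sites on linear", which
  returns the molecule whole; `digest_profile` maps it to a single
  full-length band flagged `uncut`.
* Chains that cannot close name the exact missing or duplicated junction
  code (`loop_chain_error`); enumeration blow-ups name the duplicated
  overhangs (`loop_combinatorial_cap`).
* Coordinates are 0-based half-open everywhere internally and converted to
  1-based inclusive only at the GenBank boundary; origin-wrapping features
  are stored unwrapped (`end > length`) and emitted as `join()` locations.

# Known limitations

Single-substitution domestication can fail on overlapping sites or
stop-adjacent codons (it errors rather than multi-edits); the GenBank
reader covers the flat-file subset this package writes (plus
`complement`/two-span `join`), not the full standard; receiver-free
simulation considers only release fragments (vector backbones are re-cut
indefinitely and cannot form stable products, but their transient
concatemers are real gel species the model omits); and position-1–3-only
assemblies (chains not reaching ω/F) are rejected by the planner — the
scheme defines no receiver that accepts them.
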