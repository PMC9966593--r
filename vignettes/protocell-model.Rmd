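---
title: "An agent-based model of RNA protocells with template-encoded peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of RNA protocells with template-encoded peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drtsim)
```

## The model

`drtsim` simulates a population of RNA-based protocells on an `N x N`
lattice by a discrete-time Monte Carlo method. Each room of the lattice
holds molecules — precursors and monomers of nucleotides, amphiphiles, and
amino acids, RNA strands, and dipeptides — and may carry a two-layer
amphiphile membrane, in which case the room is a protocell: its interior
and exterior are separate compartments connected only by precursor
permeation. In every step each possible event fires with a fixed
probability: monomer formation and decay, random ligation of nucleotides,
template-directed RNA replication with point mutation, RNA degradation,
membrane assembly and exchange, protocell division, fusion, breaking and
movement, and the direct RNA template (DRT) events described below. All
per-event probabilities are the model's parameters (`default_params()`);
materials are finite and conserved exactly — the package audits the
integer identity `initial + inoculated = present` for nucleotide,
amphiphile, and amino-acid equivalents after any sequence of events.

Two functional molecule kinds drive the experiments:

* **MSP**, a membrane-stabilizing dipeptide. Embedded in a membrane it
  divides the amphiphile desorption probability by `z = 1 + F_MSP * p`
  (with `p` copies embedded), so protocells able to synthesize MSP
  out-compete others for membrane material.
* **NSR / NSP**, a nucleotide synthetase ribozyme (an RNA carrying a
  10-nucleotide characteristic domain) and a dipeptide with the same
  catalytic function: either raises the nucleotide formation probability
  in its compartment from `P_NF` to `P_NFR` or `P_NFP`.

Information flows from RNA to peptide without a translation apparatus via
the DRT mechanism: an RNA carrying characteristic 5-mer binding sites
binds the corresponding free amino acids (`P_AABR` per site per step),
adjacent bound residues are ligated into a dipeptide (`P_AATL`), and the
product is released (`P_PLR`). A gene for a dipeptide is therefore a
10-mer: two concatenated binding sites. While any residue is bound the
RNA is folded: it does not replicate, degrade, or ligate — the chain is
assumed concealed in the folded structure — which creates a genuine
trade-off between serving as a replication template and as a peptide
factory.

## Closed-form kernels

Six per-step probabilities are closed forms of the state, shared verbatim
between the engine and the exported R functions:

| kernel | form | at defaults |
|---|---|---|
| membrane formation | `1 - (1 - P_MF)^(a - L_AM + 1)`, 0 below `L_AM` | 0.1 at `a = L_AM` |
| duplex separation | `P_SP^sqrt(n)` | 0.5 at `n = 1` |
| bond breaking | `P_BB` (single), squared in duplex, `x F_DO` outside | `1e-5` inside |
| division | `max(0, P_CD (1 - 2 L_AM / b))` | 0 at `b = 2 L_AM` |
| desorption | `P_ALM / [(1 + i/(b/2)^{3/2})(1 + F_MSP p)]` | 0.001 at `i = p = 0` |
| permeation (Np) | `P_NPP (b/L_AM) / (1 + i/(b/2)^{3/2})`, capped at 1 | 0.5 at `b = L_AM, i = 0` |

with movement of a polymer or complex of relative mass `m` at
`P_MV / sqrt(m)` (Zimm scaling; bound amino acids and the growing
complement count toward `m`). The desorption and permeation divisors model
the osmotic and Donnan effects of the impermeable charged species `i`
(free nucleotides plus all RNA residues, complement strands included,
inside the cell).

```{r kernels}
membrane_formation_probability(200)
amphiphile_leave_probability(b = 200, i = 1000, p = 0)
```

## The step loop

A Monte Carlo step applies five phases in a fixed order: protocell events
(break, divide, fuse, move), membrane/transport (formation, amphiphile
exchange, MSP exchange, permeation), polymer events (RNA degradation,
random ligation, template attraction / template ligation / strand
separation, DRT binding / ligation / release, peptide degradation),
monomer chemistry, and movement of free entities. Within a phase entities
are visited in randomized order and each entity undergoes **at most one
event per phase**; the listed order of polymer sub-events therefore acts
as a priority (the first event that fires claims the strand for that
step). The published event inventory does not fix an ordering; this one
was chosen so transport formulas always see start-of-step membrane state,
and `world_randomize_phases()` randomizes the phase order per step for
robustness experiments. With the forced DRT chain
(`P_AABR = P_AATL = P_PLR = 1`) this discipline is visible directly: an
empty two-site gene binds on step 1, ligates on step 2, and releases its
first peptide on step 3.

All randomness flows from a single `mt19937_64` stream seeded at world
creation, so a `(parameters, scenario, seed)` triple reproduces a run
bitwise. Independent-and-identically-distributed monomer events are drawn
as room-level binomials, which is statistically identical to per-molecule
draws.

## Replication mechanics and the fate of fragments

Template-directed synthesis proceeds by single recruitment attempts: per
step a template gains at most one substrate — a free nucleotide, or a free
unfolded strand that *pairs* at a growth site (attraction acts through
base-pairing, so only pairing-capable substrates are candidates; the
choice is uniform over candidate units). Monomer recruitment demands the
Watson–Crick partner and accepts a mismatching base with probability
`P_FP` — the model's only mutation source; the measured mutant fraction of
full-length daughters follows `1 - (1 - P_FP)^L`
(`replicate_template_once()`). Recruited substrates are segments until
template-directed ligation (`P_TL`) merges them into the growing chain.

Separation distinguishes the two kinds of paired material: an *unligated
substrate* leaves with `P_SP^sqrt(n)` of its own paired length (a 1-mer
returning to the nucleotide pool, an oligomer as the strand it was),
whereas a *ligated* complement is part of the growing chain and leaves
only once it spans the whole template, as the full complementary copy.
The distinction is load-bearing: were partially ligated complements free
to detach, most replication events would abort into short fragments and
the finite nucleotide stock would progressively lock into junk that no
longer yields full copies. With it, fragment production is limited to
chain breaking, and fragments remain useful — a complement fragment
re-anneals onto a template and is ligated into a later full copy.

Functional motifs are recognized on the sense strand only, by exact
substring match; the complement is a replication intermediate that must be
copied again to restore function, making replication genuinely two-stage.
One substitution destroys a motif. Binding sites are scanned
left-to-right without overlap.

## Compartments, containment, and boundaries

Plain movement never crosses a membrane: precursors cross only through the
permeation kernel (applied with the same expression in both directions — a
modeling choice; only the inward direction has a mechanistic derivation,
via the Donnan term), and nucleotides, RNA, amino acids, and peptides do not
cross at all. A protocell's room can still hold exterior molecules (its
bath); membrane formation encloses the room's contents at that moment.
Catalysis (NSR/NSP) acts on all precursors co-resident in the same
compartment — one functional copy upgrades the whole compartment for the
step, copies do not stack, and with both catalysts present the more
efficient one applies. The lattice boundary reflects: a move off the grid
is cancelled. Division requires a protocell-free adjacent room and assorts
every interior molecule independently with probability 1/2 — the "random
assortment" that underlies both protocell-level selection and the
function-lagging effect.

## Scenarios and reduced scales

The shipped presets (`preset()`) encode the reference experiments: spread
of MSPG protocells with a co-inoculated parasitic control gene (`fig2a`),
de novo emergence from a single gene copy in an empty vesicle (`fig2b`),
three-stage parameter turns of `F_MSP`, `P_AABR`, `P_AATL`, `P_AADE`
(`fig3_*`; turn values frozen from the published analysis, turn steps at
1/4, 1/2, 3/4 of the run since the published figure marks them only
graphically), cooperation with NSR (`fig4a`,`fig4b`), cooperation with and
takeover by NSPG (`fig5a`, `fig5b`), and the NSR-vs-NSPG efficiency
competition. Full-scale runs (`N = 30`, 50,000 of each precursor, 10^5–10^6
steps) take hours; presets accept `total_steps`, `n_grid`, and `totals`
to run reduced versions that preserve the per-room material density
(e.g. `n_grid = 10`, `totals = 5000` keeps ~50 of each precursor class
per room) and rescale event steps proportionally.

The package's test suite uses two reductions: `N = 10`, totals 5,000,
2x10^4 steps for the exhaustive conservation audit, and `N = 15`, totals
11,250, 6x10^4 steps for the replicated spread experiments — the largest
configuration whose ten-to-fifteen replicate runs stay within a test
session. The conclusions these runs support are directional: protocells
containing MSPG rise well above the ten inoculated ones and the parasitic
control gene declines steadily, ablating the MSP effect (`F_MSP = 0`)
erases the advantage, and slowing peptide turnover (`P_AADE` down)
depresses the MSPG-protocell count (the function-lagging effect). The
*absorbing* endpoints — complete extinction of the parasite and, under
ablation, of the MSPG lineage itself — are not reduced-scale observables:
extinction of a parasitic gene takes upwards of 10^5 steps at every scale,
and over such horizons a reduced population (tens of protocells, versus
~150 at full scale) is itself vulnerable to drift extinction, whereas the
inoculated membranes (10 cells of `2 L_AM` amphiphiles) are a
several-fold larger fraction of the amphiphile economy than at full
scale. Full-scale runs of the `fig2a` preset are the configuration on
which those endpoints should be read, at the cost of hours per run.

## What the generator does and does not emulate

Synthetic worlds contain everything the model defines — and only that. No
energy bookkeeping (monomers are implicitly activated), no peptides beyond
dipeptides, no random amino-acid ligation, no secondary structure
("folded" is a boolean), no real sequences: binding sites and motifs are
arbitrary distinct labels drawn once (`default_sequence_defs()`), since
only their lengths (5 and 10 nucleotides) are model-level commitments.
Consequently, passing tests show the *selection logic* — protocell-level
selection of gene-encoded function via the DRT route — is reproduced;
they say nothing about real RNA chemistry, real binding specificity, or
real membrane physics.

## Numerical and degenerate-input choices

Probabilities derived from formulas are capped at 1 (permeation at large
`b`; degradation factors). `b = 0` dissolves the protocell. A length-1
RNA is represented as a free nucleotide; strands start at length 2; a
length-1 template still carrying a paired base remains a (minimal) duplex
until separation. Gene insertion into a protocell class with no living
representative is skipped and logged, not an error. Ties and event
conflicts are resolved by the randomized visiting order; an entity
consumed in an earlier phase is never revisited in the same step.
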