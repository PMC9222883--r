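---
title: "Models and methods behind omegascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind omegascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegascan)
```

## The question the package answers

For a set of orthologous protein-coding sequences, the ratio of
nonsynonymous to synonymous substitution rates, omega = dN/dS, measures
selection pressure: omega > 1 indicates positive (adaptive) selection,
omega = 1 neutral evolution, omega < 1 purifying selection. The genetic
code makes this contrast informative: under the standard code about 96% of
single-nucleotide changes at the first codon position and essentially all
at the second alter the amino acid, while roughly two thirds of
third-position changes are silent (`classify_position_changes()` reproduces
these figures by exact enumeration, counting a change as synonymous iff
both codons encode the same amino acid or both are stops).

omegascan fits maximum-likelihood codon substitution models to an in-frame
alignment plus a phylogeny and runs the standard battery of nested
likelihood-ratio tests (LRTs), plus a per-site fixed-effects likelihood
(FEL) scan that also detects purifying selection. A task-based control
layer runs all tests — including one branch model and one branch-site model
per candidate foreground branch — in parallel with safe resume, and
compiles a per-codon report.

## The codon model

The unit of evolution is the codon: a continuous-time reversible Markov
chain on the 61 sense codons (stops are excluded from the state space).
The instantaneous rate from codon *i* to *j* is zero unless they differ at
exactly one nucleotide, and otherwise proportional to the target codon's
stationary frequency `pi_j`, multiplied by `kappa` for transitions
(A↔G, C↔T) and by `omega` when the change is nonsynonymous. Codon
frequencies default to the F3x4 estimator (position-specific nucleotide
frequencies multiplied and renormalized over sense codons); `F1x4` and
`equal` are available. Transition probabilities P(t) = exp(Qt) come from
the symmetric eigendecomposition available for reversible chains, and
alignment likelihoods from Felsenstein pruning over unique site patterns
(both in compiled code).

Rate scaling follows the convention of the model family: a single-omega
model is scaled to one expected substitution per codon per unit branch
length. In the site-class mixtures below, all classes share one scale —
the mixture-average rate — so a class with omega = 5 really does evolve
faster than a class with omega = 0.3 on the same branch. This matters: if
each class is normalized separately (a tempting implementation shortcut),
most of the between-class contrast vanishes and the tests lose nearly all
power.

## Model families and tests

* **Site models** let omega vary across codons via a mixture of site
  classes shared by all branches. M1a (classes omega0 < 1 and omega = 1)
  vs M2a (adds a free omega2 >= 1 class) is tested with df = 2, as is M7
  (beta-distributed omega on (0,1), discretized into K = 10
  equal-probability classes whose values are exact within-bin means) vs M8
  (beta plus an omega_s >= 1 class). Constraining omega_s >= 1 keeps the
  M7/M8 LRT aimed at positive selection.
* **Branch models** give the single foreground branch of a labelled
  topology its own omega. The null fixes the foreground omega at 1
  (background omega shared and free in both models), df = 1. Fixing only
  the foreground makes the test a per-branch question; the alternative
  reading (fixing omega = 1 on the whole tree) would conflate foreground
  selection with background constraint.
* **Branch-site models** use the standard four-class grid (0, 1, 2a, 2b)
  with proportions p2a/p2b = p0/p1; the alternative frees omega2 >= 1 on
  the foreground, the null pins it at 1, df = 1. The null places omega2 on
  its boundary, so the chi-squared(1) reference is the conventional,
  somewhat conservative choice.
* **FEL** is a two-stage per-site scan: an M0 fit freezes kappa, branch
  lengths and frequencies; then each codon column gets its own synonymous
  rate alpha and nonsynonymous rate beta (bounded to [0, 100]), tested
  against alpha = beta with df = 1, two-sided, with the direction read off
  the sign of beta - alpha. Its nucleotide bias is kappa-based (HKY-style),
  like the rest of the package — a leaner baseline than HyPhy's default
  GTR, so FEL site counts on real data can differ slightly from HyPhy's.

Every candidate foreground branch is enumerated
(`enumerate_foreground_topologies()`): one labelled topology per branch of
the unrooted tree — 2n - 3 for a fully resolved tree of n leaves; rooted
input is treated as unrooted (the two basal branches are one), and
polytomies contribute one topology per actual edge. Branches are
identified by the sorted leaf set they subtend, which survives
serialization and parallel execution.

Per-branch p-values are reported uncorrected, matching how such scans are
conventionally reported; a Benjamini-Hochberg column can be added by the
user from the compiled table.

## Identifying the selected sites

When a positive-selection LRT is significant, empirical Bayes posteriors
locate the responsible codons. NEB plugs in the MLEs; BEB additionally
averages over a uniform 10-point grid per mixture parameter (proportions
via stick-breaking midpoints weighted to be uniform on the simplex;
omega0 on (0,1); the positive-selection omega on (1,11); M8's beta shapes
on (0,2)), weighting grid points by their marginal likelihood. Grid
likelihoods are evaluated on the MLE's time scale — a documented
approximation that avoids refitting branch lengths per grid point. BEB is
implemented for M2a and M8; branch-site fits report NEB (BEB there costs
little statistical difference at a large computational multiple). Site
lists are conditional on the companion LRT being significant, and empty
when no fitted class has omega > 1.

## Optimization and numerics

Fits maximize the pruning likelihood with a bounded quasi-Newton optimizer
(PORT/`nlminb`) over kappa (in [0.01, 100]), the model's mixture
parameters (omega in [1e-6, 999]; proportions via stick-breaking on
[0, 1]; beta shapes in [0.005, 99]) and, by default, all branch lengths
(in [0, 50]) — input lengths are used only as starting values, mirroring
the `fix_blength -1` convention. The convergence tolerance is tied to a
parameter-improvement threshold of 5e-7. Each alternative model is
warm-started at its null's optimum *embedded exactly* (e.g. M8 at p0 = 1
over the M7 MLEs), which guarantees lnL(alt) >= lnL(null) from the first
evaluation; a second, generic interior start is always tried as well,
because a boundary start alone can leave the optimizer stuck at the null
solution. `restarts` (default 3) adds seeded, jittered starts; the seed
derives from a fingerprint of the inputs, so results are reproducible
without bookkeeping. Ties resolve to the highest likelihood, then the
lexicographically smallest parameter vector. LRT statistics are clamped at
zero (negative differences can only be optimizer noise and trigger a
warning).

Degenerate inputs are handled explicitly: alignments must be cleaned
first (`remove_gap_codons()` drops any codon column containing a gap or an
N in any sequence — frame-breaking partial gaps are an error — so that all
tests see identical data); terminal stop codons are rejected, with
`strip_terminal_stops()` as the explicit opt-in; zero-probability sites
raise an error rather than silently propagating -Inf; F3x4 frequencies are
floored at 1e-10 before building the (reversible) rate matrix.

## The simulator and what the tests show

`simulate_alignment()` draws root codons from the stationary frequencies
and evolves them along the tree under any implemented model, with site
classes drawn independently per codon (exactly the models' assumption; no
autocorrelation along the sequence, no indels, no frequency mixtures). The
same rate-scaling convention as the likelihood is used, so
simulate-then-fit recovery is exact in expectation. Two fixture trees are
built in: a three-taxon tree (outgroup plus two ingroup species, branch
lengths 0.4/0.2/0.2 substitutions per codon — a realistic short-exon
divergence for a small clade) and a 25-taxon tree (47 branches, total
length 4) that exercises foreground enumeration at gene-family scale.

Because the simulator implements the fitted models' own assumptions,
passing recovery and calibration tests demonstrates internal correctness —
the estimator finds the truth when the model is true — not robustness to
real-data violations (recombination, selection on synonymous sites,
alignment error).

`type1_power_experiment()` wraps replicated simulate-fit-test cycles. It
fits in two stages by default — M0 estimates kappa and branch lengths,
which are then frozen for the mixture fits — the standard screening
shortcut, exposed as `fit_options(fix_branch_lengths = TRUE)`; set
`two_stage = FALSE` to re-optimize branch lengths under every model. The
calibration experiment shipped in the test suite runs 200 neutral
replicates (3 taxa, 200 codons) and checks both site-model LRTs at the 5%
level, a power regime (20% of sites at omega = 5, 500 codons, 25
replicates), and M0 consistency (bias at 100 vs 1000 codons, 20 replicates
each); it uses `restarts = 0`, `max_iter = 40`, `rel_tol = 1e-8`, settings
whose p-values were spot-checked against much stricter ones (identical to
three decimals). Note that both boundary LRTs are known to be conservative
under strictly neutral data — the alternative's extra parameters sit on
the null's boundary — so empirical rejection rates near the bottom of the
nominal range are expected behaviour, not miscalibration.

## The pipeline layer

`parse_config()` reads codeml-style `key = value` ctl files (all `*.ctl`
files in the directory when none are named), applying the conventional
defaults (`CodonFreq 2`, `icode 0`, `cleandata 1`, initial `omega 1`,
`Small_Diff 0.5e-6`, ...). Keys that do not affect this native core
(`Mgene`, `rho`, `clock`, ...) are accepted, validated and recorded as
no-ops so existing ctl files keep working; unknown keys are rejected.

`run_pipeline()` expands the configuration into a deterministic task queue
(`4·[test 1] + 2B·[test 2] + 2B·[test 3] + [test h]` tasks, B = number of
branches), runs it with at most `threads` concurrent processes in two
waves (nulls first, then warm-started alternatives), and persists each
task atomically (write-then-rename plus a fingerprint marker). A restarted
run recomputes only tasks whose fingerprints do not match, and output is
byte-identical whether the run was interrupted or not and whatever the
thread count — aggregation is keyed by task id, never by completion order.
Failed tasks become rows in the summary, not exceptions. Reports comprise
the summary text, a per-codon table mapping every site result back to the
reference (first) sequence through the gap-removal column map, a FASTA
file with selected codons upper-cased, and per-branch labelled Newick
strings with p-values.

## Known limitations

Clade models, GTR nucleotide exchangeabilities, ancestral reconstruction,
indel handling and multiple simultaneous foreground branches are out of
scope. Three-taxon datasets have little per-site information: FEL
directions and empirical-Bayes site calls only become sharp with more
taxa. The chi-squared references for the boundary nulls are conventional
rather than exact. BEB for branch-site models is not implemented.
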