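# omegascan

Parallel detection of positive and negative selection on protein-coding
sequences, as a native R package.

## What it does

Comparing the rates of nonsynonymous (amino-acid-altering, dN) and
synonymous (silent, dS) substitution in an alignment of orthologous coding
sequences measures the selection pressure a protein has experienced:
omega = dN/dS > 1 signals positive (adaptive) selection, omega = 1 neutral
evolution, omega < 1 purifying selection. omegascan implements the
standard maximum-likelihood machinery for this analysis from the codon
rate matrix up:

* **Site models** M0, M1a, M2a, M7 (beta), M8 (beta + omega > 1), with the
  M1a/M2a and M7/M8 likelihood-ratio tests (df = 2 each) for positive
  selection across the phylogeny;
* **Branch models** and **branch-site models** with exhaustive enumeration
  of single foreground branches — every terminal and internal branch of the
  unrooted tree (2n − 3 for a resolved n-taxon tree) is tested in turn via
  a `#1`-labelled topology, null vs alternative, df = 1;
* **NEB/BEB empirical-Bayes posteriors** locating the positively selected
  codons when an LRT is significant;
* **FEL**, a per-site fixed-effects likelihood scan estimating a
  synonymous rate alpha and nonsynonymous rate beta per codon against the
  alpha = beta null — the one test in the battery that also detects
  *negatively* selected sites;
* a **pipeline layer**: codeml-style ctl configuration, a deterministic
  task queue run on up to `-p` threads, atomic per-task persistence with
  restart/resume, and compiled reports (summary, per-codon table,
  highlighted FASTA, p-value-annotated trees);
* a **codon-sequence simulator** under every implemented model, used for
  the package's own calibration and power tests.

The likelihood core (reversible codon rate matrix, eigendecomposition,
Felsenstein pruning over site patterns) is compiled (RcppArmadillo). All
site classes of a mixture share the mixture-average rate scale, so branch
lengths are expected substitutions per codon averaged over classes.

Inputs: an in-frame FASTA codon alignment (no stop codons, gaps removed
codon-wise — `remove_gap_codons()` does this with a column map back to the
original coordinates; the outgroup/reference goes first) and a Newick tree
whose leaf names match the FASTA headers.

## Worked example

Simulate a 120-codon alignment on a three-taxon tree in which 20% of sites
evolve under strong positive selection (omega = 6), then run the full
battery:

```r
library(omegascan)

tr <- example_tree("triplet")
sim <- simulate_alignment(simulation_spec(
  tr, "M2a", list(kappa = 2, f1 = 0.5, f2 = 0.6, omega0 = 0.2, omega2 = 6),
  ncodons = 120, seed = 7))

dir.create("demo")
write_codon_fasta(sim$alignment, "demo/aln.fasta")
writeLines(ape::write.tree(tr), "demo/tree.tre")
writeLines(c("seqfile = aln.fasta", "treefile = tree.tre"), "demo/demo.ctl")

cfg <- parse_config("demo")[[1]]
res <- run_pipeline(cfg)
cat(summary_text(res), sep = "\n")
```

```
Selection analysis summary
==========================
Dataset: demo
Alignment: 3 taxa x 120 codons (cleaned); reference: outgroup
Significance threshold: 0.05

Test 1: site models
  M1a/M2a  lnL -772.955850 vs -765.390859 | 2dlnL = 15.129981, df = 2, p = 0.000518282 *
  M7/M8    lnL -772.956116 vs -765.390903 | 2dlnL = 15.130427, df = 2, p = 0.000518167 *
  M2a NEB sites (posterior >= 0.95): 8, 39, 93
  M2a BEB sites (posterior >= 0.95): 8, 39, 93
  M8 NEB sites (posterior >= 0.95): 8, 39, 93
  M8 BEB sites (posterior >= 0.95): 8, 39, 45, 93

Test 2: branch-site models (one foreground branch each)
  [01] outgroup                       2dlnL = 4.327720, p = 0.0374964 *
  [02] speciesA                       2dlnL = 0.046598, p = 0.829093
  [03] speciesB                       2dlnL = 2.234495, p = 0.134961

Test 3: branch models
  [01] outgroup                       2dlnL = 3.581442, p = 0.0584284
  [02] speciesA                       2dlnL = 0.046839, p = 0.828657
  [03] speciesB                       2dlnL = 1.294597, p = 0.255202

Test h: FEL per-site scan
  120 codons: 0 positively, 3 negatively selected (p <= 0.05)
  negative: 10, 86, 120

Failed tasks: none
```

Reading the output: both site-model comparisons reject their no-selection
nulls decisively (2ΔlnL ≈ 15.1 on 2 df; the data were simulated with a
positive-selection class), and the NEB/BEB posteriors point at specific
codons — with M8's BEB flagging one extra site, a typical NEB/BEB
difference at this scale. The branch and branch-site tests ask a different
question — selection concentrated on one lineage — and mostly stay quiet
because the simulated selection affected all branches alike. FEL flags
three codons as purifying, which the site models cannot do. With only
three taxa, per-site calls are noisy (only a subset of the truly positive
codons reach posterior 0.95); they sharpen quickly with more species.

`run_pipeline()` also writes `summary.txt`, `codons.tsv` (one row per
codon: reference codon and amino acid, NEB/BEB posteriors, FEL
alpha/beta/p/direction, branch-site hits, original coordinates),
`highlighted.fasta` (selected codons upper-cased) and labelled Newick
trees into `demo/demo.run/`.

The same analysis from a shell:

```sh
cd demo && Rscript $(Rscript -e 'cat(system.file("exec", "omegascan", package = "omegascan"))') -p 4
```

(or put `exec/omegascan` on your PATH). `-t` selects tests (`1` site, `2`
branch-site, `3` branch, `h` FEL; default `123h`), `-s` the significance
level, `-d` keeps per-task directories, `-i`/`-c` report status / clean up,
and any `-Key value` pair overrides a ctl parameter.

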