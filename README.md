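# hemescan

Per-residue prediction of **heme-binding residues** in protein
structures, for structural bioinformaticians who have a PDB file (and,
ideally, a PSI-BLAST profile) and want to know which residues line the
heme pocket.

Heme (iron-protoporphyrin, HET code `HEM`) drives electron transfer,
oxygen transport, catalysis and signalling; mapping its binding residues
experimentally is slow.  `hemescan` combines two complementary signals
in SVM classifiers and refines the calls with spatial post-processing:

* **Structure path.**  Each residue is described by 33 numbers — 20
  logistic-scaled PSSM scores $f(x)=1/(1+e^{-x})$, relative solvent
  accessibility $\mathrm{RASA}=\mathrm{SASA}_r/\max(\mathrm{SASA}_r)$
  (Shrake–Rupley quadrature, Rost–Sander maxima), and six-statistic
  summaries of the atomic **depth index** (DPX: distance to the nearest
  solvent-accessible atom) and **protrusion index** (CX: empty/occupied
  volume ratio in a 10 Å sphere).  A *spatial window* concatenates the
  blocks of the target and its $M-1=14$ nearest Cα neighbours; an
  RBF-SVM (balanced sampling, grid-searched $C,\gamma$) makes the call.
* **Sequence path.**  A *sliding window* of $N=17$ consecutive scaled
  profile rows feeds a second RBF-SVM.
* **Post-processing.**  A predicted positive with fewer than $T=5$
  positives among its $W=18$ nearest spatial neighbours is reassigned
  negative (one pass, on the raw track); the final **ensemble** is the
  AND vote of the filtered structure call and the sequence call.

Evaluation uses recall, precision, accuracy, F1 and MCC under 5-fold
cross-validation split by protein chain.  Because curated heme datasets
need a PDB snapshot and PSI-BLAST runs, the package also ships a
generator of fully synthetic heme-protein complexes (helix-bundle
scaffolds, groove-placed porphyrin-like ligands, profiles with planted
conservation and conserved decoys) whose ground truth is known by
construction — see the methods vignette
(`vignettes/heme-binding-prediction.Rmd`).

## Worked example

```r
library(hemescan)

## a synthetic complex: 60-residue three-helix bundle, one heme,
## 8 planted binding residues
fx <- makeToyComplex(fixtureSpec(residuesPerChain = 60, patchSize = 8,
                                 seed = 7))
fx$chain
#> ChainModel 'A': 60 residues, 300 heavy atoms
#>  sequence: RKGIFGSFHHNHSGSVFGQIMFCQDHFLMCVAHAKLSRHTGHHYFLYGVNVMVLHCRVGC

## label binding residues by heavy-atom contact (4.5 A cutoff)
labeled <- labelBindingResidues(fx$chain, fx$hemes, cutoff = 4.5)
labeled
#> LabeledChain 'A': 60 residues (8 binding, 52 non-binding)
which(bindingLabels(labeled) == 1)
#> [1] 10 14 17 23 26 27 30 33

## planted conservation: mean diagonal PSSM score by class
pssm <- synthPssm(chainSequence(fx$chain), fx$truth,
                  conservationBoost = 8, seed = 7, decoys = fx$decoys)
round(tapply(conservationScore(pssm), fx$truth, mean), 2)
#>     0     1
#> -0.54  6.50
```

Binding residues come out strongly conserved (mean diagonal score 6.5
vs −0.54 for the rest), the statistical contrast the sequence path
learns.  A full cross-validated run over a 30-chain benchmark:

```r
samples <- makeBenchmark(fixtureSpec(nChains = 30, seed = 1), "bench")
cfg <- defaultConfig(seed = 1, cGrid = 2^seq(-1, 7, 2),
                     gammaGrid = 2^seq(-7, -1, 2))
run <- runCrossValidation(samples, cfg)
run$metrics[["STR_RFP+SEQ"]]$mean
#>   recall precision  accuracy        f1       mcc
#>   51.24     43.01     84.61     46.48     0.380
```

Along `STR → STR_RFP → STR_RFP+SEQ` precision rises (34.9 → 37.5 →
43.0 %) while recall falls — the filter and the vote both trade recall
for precision, the direction preferred when predictions guide
experiments.  A label-shuffled control sits at MCC ≈ 0.01.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/hemescan.R fixtures --out bench --chains 30 --seed 1
Rscript inst/cli/hemescan.R crossval --data bench --variant STR_RFP+SEQ
Rscript inst/cli/hemescan.R predict  --data bench --pdb new.pdb --pssm new.pssm
```

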