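# rna3wj

Predicting the geometry of RNA three-way junctions from secondary
structure.

Three-way junctions (3WJs) — three helical stems converging at one loop —
are the most common multi-branch motif in structured RNA, and the
orientation of their arms largely fixes a molecule's global 3D shape. Yet
even with the secondary structure known, inter-helical orientations are
hard to pin down. `rna3wj` addresses this with a dual-resolution graph
neural network: a fine-grained *nucleotide graph* (nucleotides as nodes;
backbone, base-pair and pseudoknot edges) and a coarse-grained *tree
graph* (loops as nodes, stems as edges) are encoded separately, fused by
a learned gate

&nbsp;&nbsp;&nbsp;&nbsp;*h* = *z* · *h*<sub>nucleotide</sub> + (1 − *z*) · *h*<sub>tree</sub>, &nbsp; *z* ∈ [0, 1],

refined by a two-head graph attention pass over the tree, and decoded
into the three inter-branch angles θ₁ (branches 1–2), θ₂ (2–3), θ₃ (3–1)
via a periodic sin/cos parameterization, θ = |atan2(s, c)|.

The package also provides the full geometric ground-truth pipeline —
C4′-anchor extraction from PDB/mmCIF, junction-incenter coordinates,
angle computation, rigid-star skeleton reconstruction and Kabsch-superposed
skeleton RMSD — plus a synthetic-data generator that plants recoverable
geometry so every stage is testable without downloads. Accuracy is scored
as ACC(τ): the fraction of angles (or, jointly, junctions) predicted
within a tolerance τ of the native value.

## Worked example

```r
library(rna3wj)

# parse a structure and inspect its coarse-grained topology
ss <- parse_dot_bracket("..((..((...))..((...))..))..",
                        "GGCCAAGGAAACCAAGGAAACCAAGGCC")
build_tree_graph(ss)
#> Tree graph: 4 nodes ( EMHH ), 3 stems

# a synthetic dataset with planted, recoverable junction geometry
dir <- file.path(tempdir(), "demo")
generate_dataset(synthetic_spec(count = 40, seed = 7), dir)
recs <- load_dataset(file.path(dir, "manifest.csv"))

# geometric ground-truth extraction from the emitted C4'-only PDB file
cm <- read_structure(recs[[1]]$structure_file, "A")
round(extract_junction_angles(recs[[1]]$features$tree$ss, cm)[, 1:8], 2)
#>   junction node_id theta1 theta2 theta3 len1 len2  len3
#> 1        1       2 149.53  91.92 101.54 88.4 91.2 102.4

# train on 30 chains, evaluate on 10 held-out chains
cfg <- model_config(hidden_dim = 32, lr = 0.01, max_epochs = 60, seed = 1)
model <- train_angle_model(recs[1:30], cfg)
model
#> Junction angle model (full), 7110 parameters, 60 epochs, best val loss 0.1107

pred <- predict_angles(model, recs[31:40])
truth <- do.call(rbind, lapply(recs[31:40], `[[`, "truth"))
err <- abs(as.matrix(pred[, c("theta1", "theta2", "theta3")]) - truth)
round(acc(err, c(10, 15, 20)), 3)
#>   tau acc1 acc2 acc3 overall joint
#> 1  10  0.7  0.2  0.5   0.467   0.2
#> 2  15  0.9  0.5  0.7   0.700   0.5
#> 3  20  0.9  0.8  0.7   0.800   0.7
```

The extraction table reports the three inter-branch angles (degrees) and
branch lengths (Å) of each junction; the accuracy table reports per-angle
ACC(τ), the overall (1/3N double-sum) ACC, and the joint ACC requiring
all three angles of a junction to pass simultaneously. A 60-epoch run on
30 tiny chains is only a smoke test — the methods vignette
(`vignettes/junction-geometry.Rmd`) describes the full benchmark
configuration, the model, and the synthetic generator's scope.

A command-line front end ships at `inst/cli/rna3wj.R`
(`simulate | extract | train | predict | evaluate`); after installation:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rna3wj.R", package="rna3wj"))')" \
    simulate --out sim --count 20 --seed 1
```

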