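# bdamage

Detection and quantification of **specific radiation damage** in individual
protein crystal structures, from a standard PDB or mmCIF coordinate file.

X-rays absorbed during data collection cause localised chemical changes —
disulfide cleavage, Glu/Asp decarboxylation, methionine S–C cleavage, metal
reduction — at doses well below those that visibly degrade diffraction.
Damage at a site depletes electron density and inflates the refined
isotropic B factor there, but B factors are dominated by atomic mobility,
which in turn tracks local packing. This package computes the per-atom
**B_Damage** metric, which separates the two effects by normalising each
atom's B factor against atoms in a similar crystal-packing environment:

```
B_Damage(j) = B_j / mean(B_i, i in window(j))
```

where the window contains the analysed atoms nearest to *j* in the ordering
by **packing density** — the number of non-hydrogen atoms within 7 Å of the
atom, counted in the full crystal environment (the asymmetric unit expanded
through the space-group symmetry into a 3×3×3 assembly of unit cells,
trimmed to the contact radius). Undamaged atoms score ≈ 1; candidate damage
sites stand out above. A per-structure summary, **B_net**, integrates the
B_Damage distribution of the damage-prone Asp/Glu carboxyl oxygens (its
exact published definition being deferred elsewhere, the form used here is a
documented, configurable reconstruction).

Who it is for: crystallographers assessing whether features of a model —
especially at active sites, which damage hits preferentially — might be
radiation-damage artefacts, and anyone doing large-scale B-factor-based
damage surveys of archival structures.

## Worked example

The package ships a synthetic-structure generator, so the whole pipeline
can be exercised without any input data. Here a 500-atom crystal with
realistic packing-correlated B factors carries ten planted two-fold
B-factor spikes ("damage"):

```r
library(bdamage)

fx  <- generate_damage_benchmark(n = 500, k_damaged = 10,
                                 multiplier = 2.0, seed = 1)
res <- run_bdamage(fx$path, bdam_config(outputs = c("csv", "bnet")))
res
#> B_Damage analysis of 'benchmark'
#>   500 atoms analysed; window 11; packing density 0-94 contacts
#>   B_Damage: mean 0.9997, max 1.9013
#>   B_net = 1.3947 (n = 40 OD1/OD2/OE1/OE2 atoms of ASP/GLU residues)
#>   top atoms:  ALA62:CA (1.901), ALA34:CA (1.883), ALA60:O (1.875), ...
```

The mean B_Damage sits at 1 (the metric is self-normalising), the window is
11 atoms (2% of 500, raised to the minimum), and packing densities span 0
to 94 contacts. The ten top-ranked atoms are exactly the ten spiked ones,
at B_Damage ≈ 1.6–1.9, despite their raw B factors (19–43 Å²) being
unremarkable individually — that is the point of the packing normalisation:

```r
fx$spiked_file_order
#> [1] 128 166 186 269 298 306 323 417 465 470
res$table[order(res$table$rank)[1:10], "file_order"]
#> [1] 306 166 298 186 470 323 128 417 269 465
```

`run_bdamage()` with an output directory also writes, per structure: a PDB
file with ln(B_Damage) in the B-factor column (for uniform colouring in
molecular graphics), an mmCIF file with a B_Damage column appended, a
per-atom CSV, KDE plots of the B_Damage distribution, the B_net value, and
a self-contained HTML summary. Batch analysis over many structures, driven
by a plain-text keyword configuration file, runs through `run_batch()` /
`parse_input_file()`, or from a shell via the installed `exec/bdamage`
script:

```sh
Rscript "$(Rscript -e 'cat(find.package("bdamage"))')/exec/bdamage" \
    run structure.pdb --dir out --output csv,bnet
```

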