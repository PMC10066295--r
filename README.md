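# genelossr

Gene loss is not just erosion — in lineages that transition to
multicellularity it can be a creative force, rewiring regulatory networks
and pruning gene families while complexity increases. `genelossr` is an R
package for studying that process in a clade of related genomes. It
implements three analyses end to end, plus the synthetic data to test
them:

1. **Can loss create novelty?** A Wagner-style Boolean threshold
   gene-regulatory-network simulator. A network of `N` genes updates
   synchronously by `S_i(t+1) = sigma(sum_j w_ij S_j(t))` with states in
   `{-1, +1}` and `sigma` the sign function; phenotypes are stable fixed
   points. Viable networks `(S(0), w, S_eq)` are rejection-sampled, then
   `k` genes are deleted (rows/columns zeroed, states frozen at 0) or
   duplicated (rows/columns copied, Wagner-style), and the ensemble
   measures the proportion of trials whose new equilibrium is a *novel
   stable state*: Hamming distance `d_h > k` after deletion (the `k`
   deleted positions differ by construction), `d_h > 0` over the original
   genes after duplication.
2. **Where did loss happen?** A copy-number trend scanner: for each
   orthologous group, OLS regression of per-species gene count on the
   species' branch-length distance to the in-group last common ancestor;
   the slopes are screened with Tukey fences (type-7 quartiles,
   `Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`) to call *contracting* and *expanding*
   groups.
3. **How did loss happen?** A synteny-anchored locus classifier: each
   anchor gene from a contracting group is located in every target
   species via the orthologs of its syntenic neighborhood; the bounded
   interval is scanned with a built-in tBLASTx-style engine (six-frame
   translation, affine Smith–Waterman on BLOSUM62, Karlin–Altschul
   E-values `E = K m n exp(-lambda S)`). Calls: **retained** (annotated
   ortholog), **decayed** (remnant hit with `E < 1e-5`), **deleted**
   (interval, no remnant), **non-informative** (synteny lost).
   Cross-species patterns are binned, flagged *cryptic* when they cannot
   be one single loss event on the species tree, and the mechanism counts
   are tested against a uniform expectation by chi-square GOF.

The synthetic-data module generates all inputs with planted ground truth:
count matrices with linear-in-distance Poisson means, ladder species
trees realizing arbitrary tip-to-LCA distances, and toy syntenic genomes
with planted retention / decay / deletion events written as FASTA + GFF3
+ ortholog TSV.

## Worked example

```r
library(genelossr)

## Perturbation ensembles (Wagner model)
cfg <- simulation_config(n_genes = 10, trials_per_k = 1000,
                         k_values = c(2, 5, 7), seed = 7)
run_ensemble(cfg, "deletion")
#> Perturbation ensemble (novel stable network states)
#>      mode k c trials proportion_novel_stable variance n_nonconverged ...
#>  deletion 2 1   1000                   0.202   0.1614            678
#>  deletion 5 1   1000                   0.266   0.1954            626
#>  deletion 7 1   1000                   0.311   0.2145            552
```

The proportion of deletions that push the surviving genes to a genuinely
new stable expression state *rises* with the number of genes deleted;
the same configuration in `"duplication"` mode stays near 0.20–0.24
across `k`, so intermediate-to-large losses generate more novel stable
states than equal numbers of gains. `n_nonconverged` counts perturbed
networks that fell into cycles (they count as non-novel); `variance` is
the sample variance of the per-trial novelty indicator. `plot()` draws
the two curves with a variance band.

```r
## Trend scan + loss calling on synthetic data with planted truth
syn <- make_count_matrix(count_synth_config(n_groups = 1000, seed = 1))
ts  <- classify_trends(syn$counts, syn$distances)
ts
#> Trend scan: 1000 groups, 1000 eligible; 24 contracting, 16 expanding
#> Tukey fences on rates: [-3.929, 3.957]

toy <- make_toy_genomes(genome_synth_config(seed = 42))
res <- classify_loss(toy$genomes, toy$table,
                     contracting_ids = unname(toy$groups),
                     anchor_species = toy$anchor_species,
                     species_tree = toy$tree)
res
#> Loss calls: 60 anchor loci x 5 target species (window = 5, E < 1e-05)
#>
#> Per-species calls:
#>                   sp1 sp2 sp3 sp4 sp5
#>   retained         50  51  47  49  51
#>   decayed           9   5  11   7   6
#>   deleted           1   4   2   4   3
#>   non_informative   0   0   0   0   0
#>
#> Cross-species clusters:
#>    retained_all decayed_cluster deleted_cluster
#>              35              24               1
#>
#> Decay vs deletion, chi-square GOF vs uniform: X2 = 11.077, df = 1, p = 0.000874
```

Every one of the 300 calls above matches the generator's planted truth;
decay outnumbers deletion (the chi-square line quantifies the imbalance),
mirroring how pseudogenized remnants, not clean excisions, dominate
gradual gene loss.

`run_full_pipeline(config, out_dir)` chains the stages
(synthetic data → trends → loss calling → simulation) and writes TSV/JSON
outputs plus a `manifest.json` with seeds, config hash and per-file
checksums; reruns with the same seed are byte-identical.

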