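# ruminfer

Phylogeny-based functional inference for 16S microbiome data against a
custom reference of sequenced genomes.

## The problem

Amplicon (16S rRNA) surveys tell you *who* is in a microbial community but
not *what* the community can do. Shotgun metagenomics answers the
functional question directly but at far higher cost. When a set of fully
sequenced genomes related to the community is available — for the rumen
microbiome, a few hundred cultured genomes embedded in a much larger 16S
census — the functional potential of the community can be *inferred*: gene
content is phylogenetically conserved, so an organism known only from its
16S sequence can be assigned the gene repertoire reconstructed from its
sequenced relatives. `ruminfer` implements this inference end to end for
workflows in which the reference is custom-built (not a universal
database), which is exactly the situation where a focused reference
demonstrably outperforms a generic one.

## The model

The reference is three files: a phylogeny over organisms `g` built from
16S sequences (tips split into *sequenced* and *unsequenced* genomes), a
trait table `T[g,k]` of KEGG-ortholog (KO) gene copy counts for the
sequenced tips, and a 16S copy-number table `C[g]`.

1. **Ancestral state reconstruction.** Each trait is modelled as Brownian
   motion along the tree. The ML state at a node is the
   inverse-branch-length weighted average of the messages arriving along
   its edges: a subtree with children `(x_i, t_i)` contributes `x_i/t_i`
   with weight `1/t_i`, and pruning a node adds
   `t_parent + t_a·t_b/(t_a+t_b)` to its effective length. Treating each
   internal node as the root (rerooting convention) yields its marginal
   estimate; unsequenced tips contribute nothing.
2. **Trait prediction.** Sequenced tips keep their observed rows
   (`T̂[g,·] = T[g,·]`, NSTI 0); an unsequenced tip inherits the state of
   its nearest ancestor, clamped to `≥ 0`. Reliability is tracked by the
   nearest-sequenced-taxon index (NSTI): the minimum patristic distance to
   a sequenced tip.
3. **Query pipeline.** OTU representative sequences are classified against
   the reference 16S set by global alignment identity (matches / aligned
   columns, terminal gaps excluded; default threshold 97%, inclusive);
   abundances of OTUs with a common classification are summed, divided by
   the predicted 16S copy number `max(Ĉ[g], 1)`, and pushed through the
   trait table: `M[k,s] = Σ_g (A'[g,s]/Ĉ[g]) · T̂[g,k]`.
4. **Pathway collapse.** KO profiles collapse onto KEGG BRITE level-3
   pathways, either conserving totals (each KO counted once) or fanning a
   KO out to every pathway it belongs to.
5. **Evaluation.** Predicted and observed profiles are restricted to
   their shared KOs, converted to relative abundance, and compared by
   Pearson correlation (`r`, `R²`, descriptive p).

Seeded generators (Yule trees, Brownian traits, Jukes–Cantor sequences,
Dirichlet-multinomial OTU tables) provide synthetic references and
query sets with the statistical structure the method assumes, so every
stage is testable without external data.

## Worked example

Simulate a 60-organism community in which only 18 genomes are sequenced,
predict the full trait table, run the query pipeline, and score the
prediction against the (hidden) true functional profile:

```r
library(ruminfer)

cfg <- sim_config(n_tips = 60, f = 0.3, samples = 3, depth = 2000, seed = 42)
fx  <- make_holdout_benchmark(cfg)
fx$bundle
#> Reference bundle
#>   tips:      60 (18 sequenced)
#>   KO traits: 20
#>   sequences: 60
#>   BRITE map: 45 memberships

pred <- predict_traits(fx$bundle)
pred
#> Predicted traits: 60 tips x 20 traits; mean NSTI 1.659

res <- run_profile_pipeline(fx$query$table, fx$query$seqs, fx$bundle,
                            threshold = 90)
round(res$profile[1:4, ], 1)
#>            s1     s2     s3
#> K00001 6015.7 6061.4 6080.6
#> K00002 6357.7 6313.8 6166.3
#> K00003 6294.2 6086.6 6281.6
#> K00004 6007.5 5900.6 6123.4

truth_profile <- t(fx$truth$trait_counts) %*%
  fx$query$table[paste0("otu", 1:60), ]
compare_profiles(res$profile, truth_profile)
#> Predicted vs observed profile comparison
#>   shared KOs: 20
#>   Pearson r = 0.958722  R^2 = 0.919148  p = 2.84e-11
```

The profile entries are expected KO gene counts per sample (abundance ×
predicted gene copies, after 16S copy-number correction); the comparison
shows that with 70% of the community unsequenced at a mean NSTI of 1.66
substitutions/site, the inferred functional profile still explains ~92%
of the variance in per-KO relative abundance of the true profile. A
BRITE collapse (`collapse_to_pathways(res$profile, fx$bundle$brite,
mode = "duplicated")`) aggregates the same profile at pathway grain.

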