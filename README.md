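# cgpdnet

Chemical–gene–phenotype–disease (CGPD) tetramer inference and
pesticide action-level comparison for cannabis.

## The scientific problem

Cannabis is consumed medically — often for seizure disorders and other
neurological conditions — yet the pesticides applied to cannabis crops
are regulated very differently from pesticides on food: there are no
federal residue tolerances for cannabis, and jurisdictions set action
levels that differ by orders of magnitude for the same compound.  Two
questions follow:

1. **Toxicogenomic**: which pesticide–gene interactions plausibly link
   residues to seizure-related phenotypes?  Curated pairwise evidence
   (chemical–gene, chemical–phenotype, gene–phenotype, chemical–disease,
   gene–disease) can be conjoined into CGPD *tetramers* — quadruples
   (chemical, gene, phenotype, disease) supported by all five evidence
   lines — and summarized as a tetramer-weighted bipartite
   chemical×gene network and per-function gene tables with
   epilepsy-gene overlap.
2. **Regulatory**: how divergent are jurisdictions' action levels for
   pesticide residues on cannabis, and how do they compare with federal
   reference tolerances for food?  And which qualifying conditions do
   medical-cannabis programs recognize, by category and domain?

`cgpdnet` implements both arms, plus a synthetic-data generator that
emits every required input with machine-readable ground truth, so the
entire pipeline is testable offline.

## Worked example

Simulate a CTD-like instance at default (study-condition) size, build
the tetramers, and inspect the network:

```r
library(cgpdnet)

sim <- simulate_ctd_tables(seed = 42)
ts  <- build_tetramers(sim$interactions, sim$disease)
ts
#> CGPD tetramer set
#>   disease endpoint: MESH:D012640
#>   tetramers: 175
#>   distinct chemicals: 22  genes: 56  phenotypes: 107

edges <- build_edge_list(ts)
wd <- weighted_degree(edges)
head(wd, 5)
#>        node partition weighted_degree
#> 1 MESH:C001  chemical              49
#> 2 MESH:C002  chemical              16
#> 3 MESH:C003  chemical              16
#> 4 MESH:C024  chemical              14
#> 5 MESH:C023  chemical              11

## conservation identity: edge weights sum to the tetramer count
sum(edges$weight)
#> [1] 175
```

The planted tetramer set is recovered exactly —
`sim$ground_truth$tetramers` equals `ts$tetramers` up to ordering — and
the generator verifies this by brute-force enumeration before emitting
the tables.

Regulatory statistics on the shipped illustrative fixture (synthetic
jurisdictions anchored to published endpoint values):

```r
st <- pesticide_stats(
  read_action_level_table(
    system.file("extdata", "action_levels_illustrative.csv",
                package = "cgpdnet")),
  read_reference_tolerances(
    system.file("extdata", "reference_tolerances_illustrative.csv",
                package = "cgpdnet")))
st[, c("pesticide", "n_jurisdictions", "min_level", "median_level",
       "max_level", "fold_range")]
#>             pesticide n_jurisdictions min_level median_level max_level fold_range
#> 1           abamectin               5      0.10        0.200       0.5          5
#> 2        azoxystrobin              17      0.01        0.200      40.0       4000
#> 3 chlorantraniliprole              12      0.01        0.500      40.0       4000
#> 4        dimethomorph               5      0.10        3.000      60.0        600
#> 5            ethephon               9      0.00        0.002       1.0        500
```

Note the fold-range conventions: azoxystrobin spans 0.01–40 ppm, a
4000-fold difference between jurisdictions; ethephon has a
zero-tolerance jurisdiction, so its reported minimum is 0 while the
fold-range denominator uses the limit of quantitation (LOQ).

## Command line

Each stage is also a subcommand of the shipped CLI
(`inst/exec/cgpd.R`):

```sh
Rscript inst/exec/cgpd.R simulate --seed 11 --out sim/
Rscript inst/exec/cgpd.R build-tetramers \
  --chem-gene sim/chem_gene.tsv --chem-pheno sim/chem_phenotype.tsv \
  --gene-pheno sim/gene_phenotype.tsv --chem-disease sim/chem_disease.tsv \
  --gene-disease sim/gene_disease.tsv --out tet/
Rscript inst/exec/cgpd.R network  <five input flags> --format graphml --out net/
Rscript inst/exec/cgpd.R pathways <five input flags> \
  --classes sim/chemical_classes.tsv --annotations sim/gene_annotations.tsv \
  --epilepsy sim/epilepsy_genes.txt --out paths/
Rscript inst/exec/cgpd.R residues --action-levels levels.csv \
  --reference tolerances.csv --product-type inhalable --top-k 10 \
  --mean-method arithmetic --out res/
Rscript inst/exec/cgpd.R conditions --conditions conditions.csv \
  --category-map map.csv --out cond/
```

Only `simulate` accepts (and requires) `--seed`; the analysis
subcommands are deterministic and reject it.  Every output directory
gets a `manifest.json` recording input paths, MD5 checksums, and the
package version.

### Main file formats (all plain text)

* **interaction tables** (TSV, `#` comments, optional gzip): columns
  `subject_id`, `object_id` required; `subject_ns`, `object_ns`,
  `subject_name`, `object_name`, `evidence` optional, with namespaces
  defaulting per kind (chemicals/diseases MESH, genes GENE, phenotypes
  GO).
* **action levels** (CSV): `jurisdiction`, `pesticide`, `class`,
  `product_type` (optional, default `any`), `action_level_ppm`,
  `loq_ppm` (optional).  A level of 0 ppm is a zero-tolerance rule.
* **reference tolerances** (CSV): `pesticide`, `lowest_tolerance`,
  `commodity`.
* **conditions** (CSV): `jurisdiction`, `condition`; plus a condition →
  category → domain map (CSV or YAML).

## Reproduction

`scripts/acceptance.R` runs the main computations against the
*installed* package and writes the headline quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The output includes the published-table totals computed by the
aggregation operators (183/45/46 tetramers for the
oxidation–reduction, cholinergic, and neuropeptide functions), the
fixture fold-ranges (4000/600) and zero-tolerance median (0.002 ppm),
and — for the given seed — exact-recovery indicators for planted
tetramers, residue statistics, mean fold-above-reference (planted at
32), and condition coverage, along with the network conservation
identities.  All randomness flows through `--seed`; the same seed gives
identical JSON.

Full-database outputs of a CTD analysis (e.g. hundreds of insecticide
tetramers from a specific database release) depend on that release and
are not asserted by the tests; all shipped fixtures are printed table
cells or synthetic data.  See the methods vignette
(`vignettes/cgpdnet-methods.Rmd`) for the model, numerical
conventions, and generator design.
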