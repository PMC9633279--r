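# sweepscan

Selective-sweep scans and deletion–trait association for
two-population resequencing panels.

Populations under sustained directional selection (the motivating case
is cashmere goats selected for fiber traits) carry genomic regions
where a favoured allele swept linked variation to high frequency:
locally *reduced nucleotide diversity* in the selected population and
*elevated differentiation* against an unselected reference.
`sweepscan` finds such regions from a filtered biallelic SNP panel and
takes candidates through to a trait model for a structural variant:

* **Windowed statistics** — per-bp θπ (`2j(n−j)/(n(n−1))` summed per
  window), Weir & Cockerham (1984) Fst windowed as the *ratio of
  summed variance components*, and Tajima's D, on sliding windows
  (default 150 kb / 10-kb step).
* **Joint outlier calling** — Fst is Z-transformed genome-wide; the
  diversity contrast is log2(θπ,focal / θπ,reference); windows in the
  top 1% of *both* ZFst and |log2 ratio| are outliers, merged into
  sweep regions, with genes overlapping a region or within a 500-kb
  flank annotated as candidates.
* **Confirmation** — a fine-scale profile on nonoverlapping 10-kb
  windows (ZFst, log2 ratio, Tajima's D) across any region.
* **Structure summaries** — individual p-distance matrices,
  Saitou–Nei neighbor joining with Newick output, LD decay (dosage
  r² by distance bin).
* **Association** — genotype frequency tables by population and the
  linear model `y = b0 + b·dosage + sex + batch + e` for a
  deletion allele coded 0/1/2, plus a two-locus interaction fit.
* **A synthetic generator** — two Balding–Nichols populations with a
  planted sweep and trait-linked deletion loci, so the entire pipeline
  is testable without external data.

## Worked example

Simulate the default study conditions (50+50 individuals, 20,000 SNPs
on a 10-Mb contig, background F = 0.10, a 300-kb sweep in `pop1`, two
deletion loci with 0.3 trait units per copy), then scan:

```r
library(sweepscan)

cfg <- sim_config(seed = 42)
sim <- simulate_dataset(cfg, out_dir = "demo")

gm <- read_vcf(sim$paths$vcf)
gm <- attach_metadata(gm, read_sample_metadata(sim$paths$meta))
gm <- filter_variants(gm, keep_ids = cfg$deletion_loci$id)  # biallelic,
                                    # call rate >= 0.9, MAF >= 0.05
gm
#> genotype_matrix: 100 samples x 18537 variants
#> contigs: chr1
#> populations: pop1 (n=50), pop2 (n=50)

st <- scan_windows(gm, "pop1", "pop2")      # 150-kb / 10-kb windows
cs <- select_joint_outliers(st, q = 0.01)
cs
#> sweep_callset: q = 0.01 over 986 retained windows
#> thresholds: ZFst > 6.23, |log2 ratio| > 3.99
#> 6 outlier windows in 1 merged region(s)
cs$regions
#>   chrom   start     end n_windows
#> 1  chr1 4920001 5120000         6
```

The one merged region overlaps the planted sweep
(4,850,001–5,150,000). The thresholds are recomputed from each
dataset's genome-wide distribution — they are this dataset's analog of
a printed "ZFst > ..." cutoff, not package constants. Candidate genes
within 500 kb:

```r
genes <- read_bed_genes(sim$paths$bed)
annotate_candidate_genes(cs$regions, genes, flank = 500000)
#>   region_chrom region_start region_end       gene_id gene_start gene_end
#> 1         chr1      4920001    5120000 gene_in_sweep    4975000  5025000
#> 2         chr1      4920001    5120000     gene_near    5400001  5450000
```

The third fixture gene, 800 kb away, is correctly excluded. The
in-sweep deletion allele is common in the swept population and rare in
the reference, and its dosage is tested against the trait with sex and
batch covariates:

```r
genotype_frequency_table(gm, "del_sweep")
#>   group n_called n0 n1 n2  alt_freq hom_alt_freq het_freq
#> 1  pop1       50  0 16 34 0.8400000    0.6800000 0.320000
#> 2  pop2       47 36 10  1 0.1276596    0.0212766 0.212766

associate_variant(gm, "del_sweep", "trait")
#> linear model: y ~ g1 + sex + batch  (n = 96, residual df = 92)
#>          term estimate     se      t         p
#> 1 (Intercept)  15.4934 0.2195 70.588 6.430e-82
#> 2          g1   0.2261 0.1231  1.837 6.944e-02
#> 3        sexM   0.3199 0.2109  1.516 1.328e-01
#> 4 batchbatch2   0.2162 0.2127  1.016 3.122e-01
```

The dosage estimate (0.23 ± 0.12 trait units per deletion copy) is
consistent with the planted per-copy effect of 0.3; at ~100
individuals a 0.3σ effect sits near the edge of detection, which is
why effect-recovery claims in the tests use n = 500. A fine-scale
confirmation profile for the region comes from
`fine_scale_profile(gm, "pop1", "pop2", as.list(cs$regions[1, ]))`,
and `p_distance_matrix()` + `neighbor_joining()` + `write_newick()`
reproduce the individual-level tree workflow.

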