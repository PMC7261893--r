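# pollenscan

Crossover and segregation-distortion analysis of single-pollen genotypes.

## What this is for

Genotyping individual flow-sorted, whole-genome-amplified pollen nuclei
gives direct access to a plant's male gametes, without raising a
segregating progeny. From a panel of mapped SSR/SNP markers scored on each
haploid nucleus one can (i) locate meiotic crossovers as switches of
parental origin along a chromosome, (ii) test each marker for
transmission-ratio (segregation) distortion against the Mendelian 1:1
gametic ratio, and (iii) separate *gametic* selection (distortion already
present in the pollen pool) from *gametophytic/zygotic* selection
(distortion appearing only among recovered progeny) by contrasting a
pollen-nucleus population with a sexual progeny of the same male parent.
`pollenscan` implements this analysis for geneticists working with such
panels — it was built around citrus (x = 9) single-pollen data, but any
single-parent haploid panel with a genetic map fits.

The core quantities are:

- **QC**: a gamete is retained when its positive-amplification fraction
  over the panel is at least a threshold (default 0.65).
- **Crossovers**: for gamete *g* with phased origin codes along a
  chromosome, each pair of consecutive *informative* markers (missing /
  ambiguous / off-ladder calls are skipped) is one observation; differing
  origins record a crossover in the interval, assigned to a chromosome arm
  by the centromere position. The per-interval recombination frequency is
  the crossover ratio `CO ratio = n(CO) / n(M)`, switches over informative
  observations.
- **Distortion**: per marker, `chi^2 = (A1 - A2)^2 / (A1 + A2)` on the
  transmitted-allele counts, df = 1, no continuity correction; distorted
  when p < alpha (0.05). Runs of adjacent distorted markers form
  segregation-distortion regions (SDRs).
- **Diversity**: simple-matching dissimilarity
  `d(i,j) = 1 - (1/L) * sum_l m_l` over jointly scored loci (ploidy 1),
  then a neighbor-joining tree over pooled populations.

A meiosis simulator (Haldane/Kosambi mapping functions, gametic selection
by rejection sampling, zygotic thinning, amplification dropout) generates
gamete and progeny populations with known truth, so every stage is
testable without raw instrument data.

## Worked example

The package ships the published 30-marker tangor panel (9 linkage groups,
centromere positions derived from the map's distance-to-centromere
column) and the per-marker transmitted-allele counts of a pollen-nucleus
population (n = 45–48 scored per marker) and an 86-hybrid progeny:

```r
library(pollenscan)
map <- read_marker_map(pollenscan_example("cso_map.tsv"),
                       centromeres = pollenscan_example("cso_centromeres.tsv"))
tab <- read.delim(pollenscan_example("sd_counts.tsv"))
pollen  <- sd_scan(cbind(tab[, c("locus","lg","cm")],
                         a1 = tab$pollen_a1,  a2 = tab$pollen_a2))
progeny <- sd_scan(cbind(tab[, c("locus","lg","cm")],
                         a1 = tab$progeny_a1, a2 = tab$progeny_a2))
subset(as.data.frame(progeny), distorted,
       select = c(locus, lg, a1, a2, chi_square, p_value))
#>         locus lg a1 a2 chi_square  p_value
#> 4  2P21022555  2  7 79       60.3 8.23e-15
#> 5      CX6F23  2 13 73       41.9 9.80e-11
#> 6  CIC3712-01  2 19 67       26.8 2.27e-07
#> 21    MEST107  7  4 82       70.7 4.07e-17
#> 22    MEST202  7 86  0       86.0 1.80e-20
#> 23 CIC3674-02  7 85  1       82.0 1.33e-19
distortion_rate(pollen); distortion_rate(progeny)
#> [1] 0.1333333
#> [1] 0.2
compare_populations(pollen, progeny)[c("n_union", "n_both")]
#> $n_union [1] 7    $n_both [1] 3
sd_regions(progeny, min_run = 2)
#>   lg n_markers                         loci span_min_cm span_max_cm
#> 1  2         3 2P21022555,CX6F23,CIC3712-01       57.00      114.51
#> 2  7         3   MEST107,MEST202,CIC3674-02        8.89       23.56
```

Reading: 13.3% of markers are distorted already in the pollen pool versus
20% in the progeny; three LG2 markers are distorted in both populations
(selection acting on the gametes themselves), while the LG7 region —
including a marker whose one allele class is completely absent from the
progeny (86:0) — is distorted only after fertilization, the signature of
gametophytic incompatibility or zygotic selection.

Crossover summaries work the same way from an origin matrix; from the
published chromosome-1 per-arm cross-tab of 34 lemon pollen nuclei:

```r
ct <- read.delim(pollenscan_example("eureka_arm_crosstab.tsv"))
crossover_summary(expand_crosstab(ct))
#> crossovers: 34 gametes; mean 1.97/chromosome; 14.7% without crossover;
#> max per arm (5, 4)
```

`run_all(config)` chains QC, phasing, per-chromosome crossover analysis,
distortion scans, the population contrast and the joint NJ tree, writing
TSV tables, a Newick tree, a markdown report and a manifest; a thin CLI
over the same functions is in `inst/scripts/pollenscan.R`.

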