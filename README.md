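# promshape

Promoter-by-promoter classification of chromatin state from the **shape of
H3K4me1 ChIP-seq peak density around transcription start sites (TSS)**.

H3K4me1 is usually discussed as an enhancer mark, but it is also deposited
at promoters, in one of two configurations:

- **unimodal** — a single H3K4me1 peak sitting directly on the TSS,
  coinciding with both H3K4me3 and H3K27me3. This marks **poised
  (bivalent)** promoters.
- **bimodal** — two H3K4me1 peaks displaced ~300–1000 bp on either side of
  the TSS, flanking a TSS-centered H3K4me3 peak. This marks
  **epigenetically active** promoters.

Crucially, the shape tracks the chromatin state (the joint presence of
H3K4me3 and H3K27me3) more strongly than it tracks expression level: poised
promoters keep the unimodal shape even when highly expressed, and active
promoters keep the bimodal shape even when weakly expressed.

`promshape` implements this analysis as a reusable pipeline operating on
peak calls (BED / ENCODE narrowPeak / broadPeak), a TSS catalogue (GTF or
BED6) and a kallisto-style TPM table:

1. **Geometry** — strand-aware signed distances (negative = upstream in
   gene orientation) from peak *centers* (`floor((start+end)/2)`) to the
   nearest TSS, and from each TSS to its nearest peak of each mark, with
   deterministic tie-breaking and exact brute-force-equivalent results.
2. **Density profiles** — Gaussian kernel density of peak placement,
   `f(x) = (n·h·√(2π))⁻¹ Σᵢ exp(−(x−dᵢ)²/2h²)` with bandwidth h = 15 bp on
   a ±2 kb grid, plus a center/flank shape summary (|d| < 300 bp vs
   300 ≤ |d| ≤ 1000 bp).
3. **Classification** — poised peak lists by ≥1 bp overlap of H3K4me3 with
   H3K27me3 (`-wa` semantics); two per-TSS rules: *by_k4me3* (is the
   nearest H3K4me3 bivalent?) and *by_k4me1* (does the nearest H3K4me1
   overlap a poised peak? else active if the nearest H3K4me3 center is
   within 500 bp); TPM bins B1: tpm ≤ 1, B2: 1 < tpm ≤ 5, B3: 5 < tpm ≤ 10,
   B4: tpm > 10; and the joint 2D map of (d_H3K4me1, d_H3K4me3) per TSS.
4. **Statistics** — tie-corrected Kruskal-Wallis rank sum test on
   |d(TSS, nearest H3K4me1)| across expression bins and between states.
5. **Simulation** — a seeded synthetic chromatin landscape with known
   per-promoter ground truth, emitting exactly the file formats the
   readers consume, so the whole pipeline is testable without any external
   data.

## Worked example

```r
library(promshape)

land <- simulate_landscape(landscape_config(n_genes = 500, seed = 42))
land
#> synthetic_landscape: 500 promoters on chrS ( active 300, poised 150, silent 50 )
#>   H3K4me3 : 450 peaks
#>   H3K27me3 : 150 peaks
#>   H3K4me1 : 1250 peaks
#>   H3K27ac : 300 peaks

calls <- classify_by_k4me1(land$tss, land$peaks$H3K4me1,
                           land$peaks$H3K4me3, land$peaks$H3K27me3)
table(called = calls$state, truth = land$truth$true_state)
#>         truth
#> called   active poised silent
#>   active    300      0      0
#>   other       0      0     50
#>   poised    0    150      0
```

Every promoter is recovered: the 150 bivalent promoters are called poised
because their TSS-centered H3K4me1 peak overlaps an H3K4me3∩H3K27me3
region; the 300 active promoters have a non-poised nearest H3K4me1 and an
H3K4me3 center within 500 bp; silent promoters carry no marks and fall in
`other`.

```r
d_active <- peak_to_tss_distances(land$peaks$H3K4me1,
                                  land$tss[land$truth$true_state == "active", ],
                                  warn_chroms = FALSE)
shape_summary(d_active)
#> ShapeSummary (n = 600): center (<300 bp) 0.000 | flank (300-1000 bp) 1.000 | ratio 1e+12
gaussian_density(d_active)
#> DensityProfile: n = 600 distances, bandwidth = 15 bp
#>   grid: -2000 .. 2000 bp ( 401 points )
#>   peak density 0.00099968 at offset 530 bp
```

The 600 distances (two flanking peaks per active promoter) put all of
their mass in the 300–1000 bp flank band — the bimodal signature. The rank
test separates the two states on |d|:

```r
keep <- calls$state %in% c("poised", "active") & !is.na(calls$d_k4me1)
kruskal_wallis(split(abs(calls$d_k4me1[keep]), calls$state[keep]))
#> Kruskal-Wallis rank sum test (tie-corrected)
#>   H = 299.338, df = 1, p = 4.592e-67
#>   group sizes: 300, 150
```

For real data, point `pipeline_config()` at your peak/TSS/TPM files and
call `run_pipeline(cfg, outdir)`; it writes per-mark density profiles, the
shape summary, per-TSS calls under both rules, the poised peak BED, the
joint 2D map, the grouped rank tests and a run manifest, all as headered
TSVs. A thin CLI (`inst/cli/promshape`) exposes `simulate` and `run`
subcommands.

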