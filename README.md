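# nucleocarta

Automated cartography of FISH signals in asymmetric (falciform) nuclei.

## The problem

Mapping where a chromosome territory sits inside a sperm nucleus has
traditionally meant dividing each nucleus into zones by eye and scoring
which zone a fluorescence in-situ hybridisation (FISH) signal falls in —
slow, subjective, and limited to coarse regions. Rodent sperm heads are
falciform (hook-shaped), asymmetric along both the anterior–posterior and
dorsal–ventral axes, so in principle every signal position can be oriented
unambiguously in 2D. `nucleocarta` turns that principle into an automated
pipeline for anyone quantifying nuclear organisation from 2D
epifluorescence images: cell biologists mapping chromosome territories,
and groups comparing nuclear organisation across strains or species.

## The method

For each nucleus detected in the counterstain channel, the package:

1. extracts the closed boundary outline and computes a windowed
   interior-angle profile along it; the profile's minima identify the
   **apical hook tip** and **tail attachment site** as landmarks;
2. orients the nucleus canonically (hook-to-tail chord horizontal, hook
   left, dorsal up, mirroring recorded);
3. builds a triangular mesh: landmarks plus arc-length-equidistant
   semi-landmarks as peripheral vertices, internal vertices at the chord
   midpoints of vertex pairs walked out from the tip, faces triangulating
   the bands between pairs. The mesh's graph structure depends only on the
   landmark/semi-landmark counts, so the *same* mesh is built on every
   nucleus and on the population consensus shape (the pointwise mean of
   resampled oriented outlines);
4. binarises each FISH channel within the nucleus mask and moves every ON
   pixel by the affine map `A x + b` sending its source triangle to the
   corresponding template triangle, followed by a gap-filling kernel
   (a zero pixel with ≥ 4 non-zero 8-neighbours takes their mean) and a
   clip to the template polygon;
5. composites the warped binary rasters into per-probe frequency maps
   (values in [0, 1]: the fraction of nuclei with signal at that pixel);
6. compares distributions with the multi-scale structural similarity
   index **MS-SSIM\*** — five Gaussian-windowed scales with exponents
   (0.0448, 0.2856, 0.3001, 0.2363, 0.1333), the `*` variant scoring
   zero-variance/equal-mean windows as 1, so identical images score
   exactly 1 — and measures centre-of-mass distances between
   co-hybridised probes, compared across groups with Wilcoxon rank sum
   tests.

A synthetic-fixture module generates falciform nuclei with planted
signals and full ground truth, so every stage is testable without
microscopy data. See the methods vignette
(`vignettes/nuclear-cartography.Rmd`) for the model details and design
decisions.

## Worked example

Simulate a 40-nucleus population with a sex-chromosome-style probe planted
dorsal-apically and an autosome-style probe ventral-basally, then run the
full pipeline:

```r
library(nucleocarta)

strains <- list(list(
  params = falciform_params(strain_label = "PWK"),
  signals = list(planted_signal("chrX", "dorsal_apical"),
                 planted_signal("chr19", "ventral_basal"))))
pop <- generate_population(strains, n_per_strain = 40, seed = 1)

records <- detect_and_orient(pop$fields)   # 40 nuclei recovered
res <- warp_population(records, pop$fields, pop$probe_map)

res$composites$chrX
#> <composite_map> chrX: 96x54 px, n=40, max freq 0.925
res$composites$chr19
#> <composite_map> chr19: 96x54 px, n=40, max freq 0.950

round(similarity_matrix(res$composites), 3)
#>        chrX chr19
#> chrX  1.000 0.112
#> chr19 0.112 1.000

d <- population_distances(records, pop$fields, pop$probe_map)
summary(d$distance_um)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   3.555   4.427   4.826   4.813   5.200   5.907
```

Reading the numbers: both composites peak above 0.9 — more than 90% of
nuclei carry signal at the modal pixel of each territory — while the
MS-SSIM\* of 0.112 between the two probes confirms the dorsal-apical and
ventral-basal territories are nearly disjoint. The centre-of-mass
distances (median 4.8 µm in a ~10 µm nucleus) quantify the same
separation per nucleus. `render_composite_png()` writes the composites as
cividis-palette heat maps.

The same workflow is scriptable from a shell via the installed CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/nucleocarta", package="nucleocarta"))') \
    simulate --config run.yaml --seed 1 --out run_out
# then: detect, warp, compare with the same config
```

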