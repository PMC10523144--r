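# IsletRadius

Semi-automated quantification of endocrine cell localization and
distribution in pancreatic islets of Langerhans, from stained section
images.

Rodent islets normally show a mantle–core architecture: insulin-producing
beta cells in the centre, glucagon-producing alpha cells and
somatostatin-producing delta cells at the periphery. Metabolic disease can
remodel this arrangement, and judging it by eye does not scale. IsletRadius
turns the question "how far from the islet centre do the hormone-positive
cells sit?" into a per-pixel statistic that can be averaged per islet,
exported, and tested.

## The statistic

For an islet delimited by a user-drawn boundary polygon with vertices
$(x_j, y_j)$ and centre $c$ (the vertex mean), every hormone-positive pixel
$p$ detected by thresholding is assigned a **relative radius**

$$\mathrm{rr}(p) \;=\; 100 \cdot \frac{\lVert p - c \rVert}{R(\theta_p)}\ \%,$$

where $\theta_p$ is the polar angle of $p$ about $c$ and $R(\theta)$ is the
boundary radius along the same direction, obtained by **linear
interpolation of the polygon vertices in polar coordinates** — the vertex
radii $r_j$ interpolated as a function of the vertex angles $\phi_j$, with
circular wraparound. Values near 0 mean central localization, values near
100 peripheral localization.

This construction requires the vertex angles to be weakly monotonic about
the centre (up to one cyclic wraparound); convex polygons always are.
Polygons violating it are repaired by sorting the vertices by angle, the
repair is reported, and — because the repair changes the drawn shape —
relative radii above 100 % can then occur. Those are excluded from the
per-islet mean and the exclusion percentage is reported alongside. Islets
with no staining are flagged and never averaged as 0. Each islet also gets
a **relative area**: the percentage of islet pixels (pixel centres inside
the polygon, even-odd rule) that are hormone-positive.

Detection is plain thresholding: an HSV colour box for the earthy red-brown
DAB chromogen in immunohistochemistry (`ihc` mode), an intensity threshold
(fixed or per-image Otsu) for immunofluorescence (`if` mode). DAPI support
images in a `support/` subfolder are matched by a three-character filename
prefix and contrast-stretched **for display only** — they never influence
the computed results.

## Worked example

Relative radii on the unit square with centre (0, 0):

```r
library(IsletRadius)
sq <- IsletPolygon(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
as.data.frame(relativeRadii(sq, rbind(c(0, 0), c(0.5, 0), c(1, 1))))
#>     x y     theta        r rBoundary relRadius
#> 1 0.0 0 0.0000000 0.000000  1.414214   0.00000
#> 2 0.5 0 0.0000000 0.500000  1.414214  35.35534
#> 3 1.0 1 0.7853982 1.414214  1.414214 100.00000
```

The centre scores 0 %, a polygon vertex 100 %. The point (0.5, 0) scores
100·0.5/√2 ≈ 35.36 % — not 50 % — because the interpolated boundary of a
square is the constant vertex radius √2, not the edge: the statistic is
defined by the angular interpolation, which converges to the true boundary
as the polygon gains vertices (a drawn islet border has many).

A synthetic cohort of 5 peripherally stained ("mantle") islets, analysed
end to end and exported:

```r
dir <- file.path(tempdir(), "islets")
simulateCohort(5, "mantle", "ihc", dir = dir, seed = 42)
res <- analyzeFolder(dir, "ihc", outPrefix = file.path(dir, "results"))
res[, c("image_id", "n_cell_pixels", "relative_area_pct",
        "mean_relative_radius_pct", "pct_excluded")]
#>        image_id n_cell_pixels relative_area_pct mean_relative_radius_pct pct_excluded
#> 1 islet_001.png           284             1.194                    90.47            0
#> 2 islet_002.png           277             1.465                    90.00            0
#> 3 islet_003.png           277             1.760                    90.08            0
#> 4 islet_004.png           276             1.137                    89.54            0
#> 5 islet_005.png           272             2.357                    90.07            0
```

The generator placed cell blobs at relative radii drawn uniformly on
0.85–0.95, and the pipeline recovers per-islet means near 90 % with no
radii excluded. `results.csv` and `results.xlsx` hold the same table;
`results.run.json` carries the run metadata (config fingerprint, timestamp,
version).

A command-line front end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/isletradius.R", package="IsletRadius"))')" \
    simulate --phenotype mantle --n 20 --mode ihc --seed 7 --out cohort/
Rscript .../isletradius.R analyze cohort/ --mode ihc --out results
```

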