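# lcscreen

Rapid screening and documentation of likely **Least Concern (LC)** plant
species for IUCN Red List assessment.

Most of the world's plant species have never been assessed for the Red
List, and the scarce pool of trained assessors is best spent on species
likely to be threatened. `lcscreen` addresses the other side of the triage:
it identifies species whose geographic range, estimated from aggregated
occurrence records restricted to their documented native range, is so large
that a threatened or Near Threatened category is implausible — and it
generates the complete documentation bundle those species need for batch
publication through the IUCN SIS Connect channel.

It is aimed at Red List assessors, specialist groups and conservation
practitioners who want to deprioritise non-threatened species quickly, with
every step runnable offline against fixture backends.

## Method

For each species the pipeline:

1. **Resolves the binomial** against a name backbone (fuzzy matching,
   confidence-ranked candidates; synonyms are excluded from batch analysis
   and reported with their accepted name).
2. **Retrieves the native range** as a set of WGSRPD Level-3 "botanical
   country" codes from a checklist provider, distinguishing native from
   introduced regions.
3. **Fetches and cleans occurrences** (georeferenced, issue-free records;
   coordinate bounds, (0,0) sentinel removal, exact-duplicate collapse) and
   **discards every record outside the native Level-3 polygons** —
   uncritical use of aggregated occurrences inflates range metrics with
   introduced and erroneous records.
4. **Computes four range statistics** on a per-species cylindrical
   equal-area projection (centred on the points' centroid):
   - `EOO` — extent of occurrence, the area (km²) of the minimum convex
     polygon of the retained points;
   - `AOO` — area of occupancy, occupied 10 km × 10 km grid cells × 100 km²
     (a coarse screening scale, deliberately broader than the IUCN 2 km
     reference scale, to absorb georeference error);
   - `RecordCount` — unique retained coordinate pairs;
   - `TDWGCount` — native Level-3 regions actually occupied.
5. **Classifies** the species as likely LC iff every statistic meets or
   exceeds its threshold (defaults `EOO ≥ 30,000 km²`, `AOO ≥ 3,000 km²`,
   `records ≥ 75`, `regions ≥ 5`) and no warning was raised.
6. **Exports** the seven cross-linked SIS Connect CSVs (`allfields`,
   `assessments`, `countries`, `credits`, `habitats`, `plantspecific`,
   `taxonomy`, keyed by `internal_taxon_id`) plus the point-distribution
   CSV, zipped for upload.

Threshold defaults can be re-calibrated for any taxon set with
`sweep_all()`, which scores LC-vs-not predictions against published
categories over a threshold continuum using confusion matrices (TP/FP/TN/FN,
accuracy, TPR, FPR). Range-based screening cannot catch widespread species
threatened across their whole range (e.g. by over-exploitation), which is
why classification output is a *suggestion* requiring operator acceptance
(`accept_lc`) before any bundle is written.

## Worked example

Using the bundled offline fixtures (a small name backbone, checklist and
occurrence store with toy rectangular region geometries):

```r
library(lcscreen)
fd <- bundled_fixture_dir()
bb <- read_name_backbone(file.path(fd, "name_backbone.json"))
rp <- read_range_provider(file.path(fd, "native_ranges.json"))
ob <- read_occurrence_backend(file.path(fd, "occurrences.json"))
st <- read_region_store(file.path(fd, "regions_toy.geojson"))

res <- run_single("Aloe zebrina", bb, rp, ob, st)
res$results
#> # A tibble: 1 x 8
#>   full_name    powo_id      eoo_km2 aoo_km2 record_count tdwg_count least_concern warning
#>   <chr>        <chr>          <dbl>   <dbl>        <int>      <int> <lgl>         <chr>
#> 1 Aloe zebrina urn:lsid:i... 4.35e6    2100           21          7 FALSE         ""
```

Read: the fixture's 21 native-range records span an extent of occurrence of
about 4.35 million km² across 7 Level-3 regions — comfortably above the EOO
and region thresholds — but only 21 unique records occupying 21 grid cells
(AOO 2,100 km²), below the record-count (75) and AOO (3,000 km²)
thresholds, so the species is *not* suggested as Least Concern at the
defaults. `res$gauges` shows the per-parameter pass flags.

The same workflows are scriptable from a shell:

```sh
Rscript inst/scripts/lcscreen.R single --name "Aloe zebrina"
Rscript inst/scripts/lcscreen.R batch --names names.csv --accept-lc --out-dir out/
Rscript inst/scripts/lcscreen.R sensitivity --validation records.csv --out-dir out/
```

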