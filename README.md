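# platewell

`platewell` is a scriptable laboratory-information toolkit for microplate
assays, aimed at labs that run dose–response experiments — compound
profiling, cytotoxicity panels (e.g. FMCA-style cell-viability assays),
secondary screening — and want the plate-design, data-import, curation and
IC50 steps to live in reproducible code instead of spreadsheets.

The package models the stepwise way plates are actually made:

```
PlateType  ->  PlateLayout  ->  MasterPlate  ->  Plate (barcoded)
(geometry)     (markers +       (substances +    (raw data, outliers,
                formulas)        dilutions)       report)
```

* **Layouts** name groups of wells — *control*, *blank* and *substance*
  markers — and carry Excel-like calculation formulas: per-well functions
  such as a survival index
  `SI% = (value − avg(BLANK)) / (avg(CTRL) − avg(BLANK)) × 100`,
  and per-plate functions such as screening Z-score ingredients. Placing a
  control or blank marker auto-registers `avg(G)` and `sd(G)`.
* **Import** reads plate-reader files (a line-oriented reader-log dialect
  and plain CSV), matches blocks to plates by **barcode**, and guards
  against double import.
* **Curation** marks wells as outliers, which removes them from every
  aggregate, QC statistic and dose–response point.
* **QC**: control CV% (per group and pooled over all controls) and
  Z-scores over any well set.
* **Dose–response**: per-substance curves of mean SI% per concentration;
  IC50 by the default *linear interpolation* — the two adjacent points
  closest to 50% that bracket it, interpolated on the log10 concentration
  axis — or by non-linear least-squares fit of the four-parameter Hill
  equation `f(c) = bottom + (top − bottom) / (1 + (c/IC50)^h)`.
* **Store**: an audited JSON document store (creator + timestamp, soft
  delete, admin-only undelete, tree listing).
* **Simulator**: synthetic plates with known true curves, Gaussian noise,
  optional spatial drift and edge-well artifacts, for end-to-end
  validation.

A command-line workbench (`exec/platewell`, a thin wrapper over
`pw_main()`) exposes the same workflow as shell subcommands
(`plate-type`, `layout`, `master`, `plate`, `import`, `outlier`, `report`,
`simulate`, `ls`, `delete`/`undelete`, `user`).

## Worked example

```r
library(platewell)

pt  <- plate_type("std96", rows = 8, cols = 12)          # 96 wells
lay <- plate_layout("fmca-v1", pt)
lay <- place_marker(lay, "CTRL",  "control",   paste0("B", 2:11))
lay <- place_marker(lay, "BLANK", "blank",     paste0("C", 2:11))
lay <- place_marker(lay, "S1",    "substance", paste0("D", 2:9))
lay <- add_well_function(lay, "SI",
  "(value - avg(BLANK)) / (avg(CTRL) - avg(BLANK)) * 100", paste0("D", 2:9))

mp <- master_plate("batch-07", lay, list(
  S1 = list(substance = substance("melphalan"),
            series = dilution_series(100, sqrt(10), 8, unit = "uM"))))
plate <- create_plate(mp, barcode = "P0001", name = "run1",
                      sample = assay_sample("cell_line", "CEM"))

# attach raw reader values (normally via read_reader_log() + attach_results())
conc <- expand_dilution_series(dilution_series(100, sqrt(10), 8))
raw  <- 100 + 1000 / (1 + conc / 3)        # a clean IC50 = 3 uM curve
plate <- set_raw_values(plate, c(
  setNames(rep(1100, 10), paste0("B", 2:11)),
  setNames(rep(100, 10),  paste0("C", 2:11)),
  setNames(raw, paste0("D", 2:9))))

(curve <- build_dose_response(plate, "melphalan"))
#> <dose-response> melphalan: 8 points (SI % vs uM)
#>  concentration mean_response n sd
#>     0.03162278     98.956903 1 NA
#>     0.10000000     96.774194 1 NA
#>     0.31622777     90.464233 1 NA
#>     1.00000000     75.000000 1 NA
#>     3.16227766     48.683298 1 NA
#>    10.00000000     23.076923 1 NA
#>    31.62277660      8.664816 1 NA
#>   100.00000000      2.912621 1 NA
ic50_linear(curve)
#> [1] 2.985269
ic50_hill(curve)
#> <Hill fit> ic50 = 3, slope = 1, top = 100, bottom = -1.924e-07, rss = 2.392e-14
control_cv(plate)
#> <CV% report>
#>   CTRL           0
#>   pooled         0
```

Reading: the half-log dilution series gives 8 points of survival index; the
piecewise-linear estimate crosses 50% at 2.99 µM (grid-limited, the true
half-maximal point of this curve is 3 µM), and the Hill fit recovers IC50 =
3 µM, slope 1, top 100 / bottom 0 essentially exactly because the data are
noiseless. Control CV% is 0 since all control wells are identical here.

`write_plate_report(plate, "run1.json", ic50_method = "both")` emits the
full deterministic plate report (wells, evaluated functions, CV%, curves,
IC50s) as JSON or sectioned CSV.

## File formats

The reader-log dialect, the CSV raw-data layout, the store document schema
and the report formats are documented in [docs/formats.md](docs/formats.md).
The methods vignette (`vignettes/platewell-methods.Rmd`) describes the
statistical procedures, the simulator and the package's design decisions.
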