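# File formats

## Reader-log dialect (`read_reader_log()`, `write_fixture_files(format = "log")`)

A line-oriented text format for one or many plate reads per file:

* Blocks are separated by one or more blank lines; each block is one plate
  read.
* An optional first line `ID1: <barcode>` carries the plate barcode. If it
  is absent the read has no barcode and must be matched via the
  `barcode_overrides` list during import (in file order).
* Every other line is `<well label><TAB><value>`, e.g. `B3<TAB>1042.7`.
  Well labels are A1-style (row letter, 1-based column number) and are
  validated against the declared plate geometry. Values use the `.`
  decimal separator only; anything else (including `,` decimals) is a
  parse error with a line number. Duplicate wells within a block are
  rejected.

Example (two 2-well blocks, the second without a barcode):

```
ID1: P0001
A1	981.2
A2	1043.5

B1	55.0
B2	61.3
```

This dialect is project-defined: it models the shape of multi-plate
reader exports (block-per-plate, barcode header, well/value lines) without
claiming compatibility with any vendor's proprietary layout. Additional
dialects can be added behind the same reader interface (a function
returning a list of raw reads). A committed example,
`inst/extdata/example-run.log` (two simulator-generated 96-well plates),
is parsed by the test suite.

## CSV raw data (`read_csv_plate()`, `write_fixture_files(format = "csv")`)

RFC-4180-style CSV with a header row and columns `barcode`, `well`,
`value`. Rows sharing a barcode form one read; rows with an empty barcode
are grouped into reads by contiguous runs. Duplicate `(barcode, well)`
pairs and non-numeric values are format errors with a row number.

## Store layout (`store_open(path)`)

```
<root>/users.json                      registered users
<root>/<type>/<sanitized-name>.json    one document per resource
<root>/config.json                     optional CLI defaults (user, ic50)
```

Resource types: `plate_type`, `plate_layout`, `master_plate`, `plate`,
`substance`, `sample`. Each document is

```json
{ "schema_version": 1, "type": "...", "name": "...", "resource": { ... } }
```

where `resource` uses a tagged encoding that round-trips R values exactly:
every node carries `_type` (`list`, `data.frame`, `double`, `integer`,
`logical`, `character`, `null`), lists may carry `_class` and `names`,
data frames carry their `columns`, and doubles travel as
17-significant-digit strings so that reopening a store reproduces every
field bit-for-bit. Audit fields (`creator`, `created_at`, `deleted`,
`deleted_by`, `deleted_at`) live under `resource.audit` and are written
once; deletion only flips the flags — documents are never removed.

## Plate report (`write_plate_report()`)

* **JSON**: the `plate_report()` object — plate identity, the wells table
  (raw value, outlier flag, one column per evaluated well function),
  per-group and pooled control `cv`, every plate-function value, and one
  `dose_response` entry per substance with its points, `ic50_linear`
  (plus a `reason` code such as `no_crossing` when undefined) and the
  Hill fit when enabled.
* **CSV**: the same content as a sectioned file; section headers are
  `[plate]`, `[wells]`, `[cv]`, `[plate_functions]` and one
  `[dose_response <substance>]` per substance.

Reports contain no timestamps and are byte-deterministic for a given
plate, so re-running a report can be verified with a plain diff.
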