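# Packaged reference tables

Plain-text (TSV) reference tables from the original 133-subject resting-state
study that this package's methods were developed on. They let the selection
stages (emerging links, centrality index, principal/secondary vertices) be
exercised and cross-checked without any imaging data. The subject-level
scans are not deposited anywhere, so the intensity and centrality values
here are *inputs*, not quantities the package can recompute.

| file | content |
|---|---|
| `atlas.tsv` | 94 Harvard-Oxford cortical nodes: node id, hemisphere, region name (1-47 left, 48-94 right) |
| `cohort_groups.tsv` | the 14 age/sex groups: age range and male/female counts (51 M, 82 F, 133 total) |
| `merged_groups.tsv` | the 7 merged age groups used by the statistical analysis (printed labels; `age_lo`/`age_hi` give the actual merged coverage) |
| `link_frequencies_{male,female}.tsv` | emerging links L with their frequency of appearance over the 14 group networks |
| `link_intensities_{male,female}.tsv` | per-group FD intensities of the emerging links (columns g1..g14) |
| `centrality_{male,female}.tsv` | centrality index CI(v) per node with at least one surviving link |
| `representative_vertices.tsv` | the published principal (V') and secondary (V'') vertex sets |

Known print defects carried over from the source tables, and how they are
handled here:

- male link 28-75, group g7: printed as `45`, stored as `0.45`
  (decimal-point error; every other intensity lies in [0, 1]).
- female link 1-48: printed frequency 11 but 12 nonzero intensities;
  female link 69-78: printed frequency 12 but 11 nonzero intensities
  (the two frequencies appear swapped in print). Both files store the
  values exactly as printed; consistency tests therefore pin the male
  table (fully consistent) and the female row 29-76.

Access from R with `load_fixture()`, which parses each file into a tibble.
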