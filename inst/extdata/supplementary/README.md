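# Optional: published differential-peak coordinate tables

The acceptance test "cross-assay merging of the published
differential-peak tables reproduces the printed overlap" replays
`cross_assay_merge()` on the published differential peak sets of the two
assays and compares the merged count against the printed value (161).
Those coordinate tables are distributed as journal supplementary XLSX
files and are not redistributable here.

To run that comparison, export the two coordinate tables as CSV with
columns `scaffold,start,end` (0-based half-open starts, one peak per
row) into this directory as:

- `supplementary_atac_diff.csv`  — ATAC-seq differential peaks
- `supplementary_dnase_diff.csv` — DNase-seq differential peaks

Absent these files the test reports the tables as unavailable and fails;
every other test is self-contained.
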