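paired_islet_donor_metrics.tsv

Published per-donor summary metrics from the four-donor paired islet
scRNA-seq/snRNA-seq study design this package targets: per-sample intronic
read percentage, median features per barcode (after the initial feature /
barcode / doublet filters), and median mitochondrial gene percentage
(values printed as "< 0.001" are recorded as 0). One row per donor and
modality. Used by scripts/acceptance.R and the analysis drivers to compute
donor-level Hodges-Lehmann shifts.
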