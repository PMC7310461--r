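# Layout of the six-dataset, three-platform SLE PBMC compendium:
# one row per expression series with its platform and per-group sample
# counts. The per-platform subject totals derived from this file are the
# mixture weights N_j used when merging per-platform contrasts.
datasets:
  - {dataset_id: GSE17755,  platform_id: Hitachisoft, n_case: 22, n_control: 55}
  - {dataset_id: GSE12374,  platform_id: Hitachisoft, n_case: 11, n_control: 6}
  - {dataset_id: GSE50772,  platform_id: Affymetrix,  n_case: 61, n_control: 20}
  - {dataset_id: GSE81622,  platform_id: Illumina,    n_case: 30, n_control: 25}
  - {dataset_id: GSE121239, platform_id: Affymetrix,  n_case: 65, n_control: 20}
  - {dataset_id: GSE126307, platform_id: Illumina,    n_case: 31, n_control: 9}
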