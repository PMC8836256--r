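# Demo pipeline configuration: simulates the full five-group study
# design with planted stage-specific effects and six corrupted subjects,
# then runs QC, TMM normalization, all seven pairwise contrasts,
# stage-specific set calling, biomarker panels, pathway enrichment on
# the bundled synthetic fixtures, the serum-CSF comparison, and qPCR
# validation of the top two RRMS-specific markers.
seed: 1
simulate:
  n_outliers: 6
  outlier_severity: 1.0
qc:
  min_count: 10
  min_fraction: 0.5
  outlier_rule: tukey
normalize:
  prior_count: 0.5
de:
  engine: ql
  p_threshold: 0.01
  lfc_threshold: 1.0
  contrasts:
    - "CIS:HealthCtl"
    - "CIS:HospCtl"
    - "RRMS:HealthCtl"
    - "RRMS:HospCtl"
    - "VI:HealthCtl"
    - "VI:HospCtl"
    - "RRMS:CIS"
enrichment:
  alpha: 0.01
  min_mirnas: 3
csf:
  high_serum_fraction: 0.0595
  offset_log10: 2
  noise_sd: 0.2
qpcr:
  replicate_sd: 0.2
  outlier_rate: 0.05
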