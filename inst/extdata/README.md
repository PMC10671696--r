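# Packaged data files

- `fh-config.yaml` — default configuration: criterion thresholds and point
  tables, the MEDPED total-cholesterol table, the statin/ezetimibe
  treatment-intensity factor table, Friedewald reporting rules and variant
  classification rules. Load with `fh_default_config()`; copy and edit, then
  load with `fh_read_config()`.

- `ldlr_variants.tsv` — the 22-row LDLR variant spectrum table (HGVS cDNA
  notation, protein change, localization, per-proband and cascade counts,
  clinical-significance annotation carried as-is, novelty flag). Known count
  quirks are reported, not resolved, by `spectrum_summary()`: the proband
  counts sum to 25 observations while 18 single-variant plus 4
  compound-heterozygous cases would imply 26, and the study reports 25
  distinct variants overall although only 22 are individually listed (the
  other 3 cannot be recovered from the published table).

- `adult_cohort_synthetic.csv` — a 31-subject **synthetic** adult cohort
  (16 genotype-positive probands, 10 positive cascade relatives, 3 negative
  probands, 2 negative cascade relatives). Not patient data: subjects were
  constructed (see `data-raw/adult_cohort.R`) so that evaluating the
  packaged criteria reproduces the study's published per-criterion confusion
  matrices exactly while matching the published stratum means (pretreatment
  LDL-C and TC, peak LDL-C, family pCVD history rates). Load with
  `fh_adult_cohort()`.
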