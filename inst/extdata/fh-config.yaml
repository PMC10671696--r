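# Default configuration for fhdx: criterion thresholds, point tables and
# lipid-lowering correction factors. All lipid concentrations are mmol/L.
# Every threshold comparison on LDL-C / TC is strict (">") unless a key says
# otherwise. Edit a copy of this file and load it with fh_read_config().

units: mmol/L

dlcnc:
  # Point items of the Dutch Lipid Clinic Network score. Within each group
  # only the highest applicable item counts.
  family_history:
    first_degree_pcvd: 1
    first_degree_hyperlipidemia: 1
    child_under18_high_ldl: 2
  clinical_history:
    premature_cad: 2
    premature_cerebral_or_peripheral: 1
  physical_signs:
    tendon_xanthoma: 6
    arcus_under_45: 4
  dna_variant: 8
  # LDL-C bands: points awarded at the lowest threshold the value reaches
  # (>= lower bound). Original instrument bands.
  ldl_bands:
    - {min: 8.5, points: 8}
    - {min: 6.5, points: 5}
    - {min: 5.0, points: 3}
    - {min: 4.0, points: 1}
  # Chinese-modified LDL-C bands (lower cutoffs, higher sensitivity).
  ldl_bands_modified:
    - {min: 6.0, points: 8}
    - {min: 5.0, points: 5}
    - {min: 3.5, points: 3}
    - {min: 2.5, points: 1}
  categories: {definite_gt: 8, probable_min: 6, possible_min: 3}
  binary_cutoff: 3            # score >= cutoff => positive call
  pediatric_policy: flag      # flag | suppress : DLCNC is not validated <18 y

simon_broome:
  ldl_cutoff_adult: 4.9       # strict >
  ldl_cutoff_child: 4.0
  # definite requires tendon xanthomata (subject or relative) or a DNA variant
  relative_xanthoma_counts: true

medped:
  # Published MEDPED total-cholesterol thresholds (mmol/L), strict ">".
  # Age bands: <20, 20-29, 30-39, >=40.
  age_breaks: [20, 30, 40]
  thresholds:
    first_degree:  [5.7, 5.9, 6.2, 6.7]
    second_degree: [5.9, 6.2, 6.5, 6.9]
    third_degree:  [6.2, 6.5, 6.8, 7.2]
    general:       [7.0, 7.5, 8.8, 9.3]

jfhmc:
  ldl_cutoff_adult: 4.7       # heterozygous pattern, strict >
  ldl_cutoff_child: 3.6
  hofh_tc_cutoff: 15.5        # total cholesterol, strict >

hk_panel:
  adult_ldl: 5.0              # strict >
  adult_ldl_with_history: 4.5 # with family history of FH or pCVD
  child_ldl_with_history: 3.6
  child_ldl: 4.9

ldl_selection:
  policy: pretreatment_first  # pretreatment_first | peak
  max_plausible_mmol: 30      # above this, input is probably mg/dL

intensity_criterion:
  threshold: 1.8              # treatment intensity >= threshold
  reduction_band: [0.40, 0.70] # observed fractional LDL-C drop "around 50%"
  ldl_cutoff_combined: 5.5    # pretreatment LDL-C >= cutoff, combined rule

friedewald:
  tg_max: 4.5                 # LDL-C not reported when TG > 4.5 (strict >)

# Treatment-intensity factor table. intensity = 1 / (1 - expected fractional
# LDL-C reduction) for each drug/dose; statin and ezetimibe factors combine
# multiplicatively by default. Doses are mg/day. Anchors: Simvastatin
# 40-80 mg -> 1.7-1.9; Atorvastatin 20 mg and Rosuvastatin 5 mg -> ~1.8.
correction_factors:
  combination_rule: multiplicative
  untreated_intensity: 1.0
  drugs:
    simvastatin:   {10: 1.429, 20: 1.538, 40: 1.724, 80: 1.887}
    atorvastatin:  {10: 1.587, 20: 1.786, 40: 2.000, 80: 2.222}
    rosuvastatin:  {5: 1.818, 10: 2.000, 20: 2.222, 40: 2.500}
    pravastatin:   {10: 1.250, 20: 1.316, 40: 1.408, 80: 1.493}
    fluvastatin:   {20: 1.266, 40: 1.370, 80: 1.493}
    lovastatin:    {10: 1.266, 20: 1.408, 40: 1.587}
    pitavastatin:  {1: 1.471, 2: 1.563, 4: 1.695}
    ezetimibe:     {10: 1.200}

variant_rules:
  # consequence -> expected receptor class
  receptor_class:
    splice: negative
    frameshift: negative
    nonsense: negative
    synonymous_splice: negative
    missense: defective
  near_splice_window: 5       # intronic offset |n| <= window counts as splice

reporting:
  percent_digits: 1           # percentages rendered half-up to one decimal
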