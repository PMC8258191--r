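# Survey table layouts

All tables are UTF-8 CSV with "." as the decimal separator. Masses are in mg,
lengths in µm throughout; unit conversion happens only inside allometric
formula evaluation.

## weighings.csv
| column            | type    | description |
|-------------------|---------|-------------|
| sample_id         | string  | station_id x event_id, e.g. "C_E5" |
| taxon_name        | string  | empty for control boats |
| stage_tag         | string  | optional; "nauplii"/"copepodites" for Calanus |
| n_individuals     | integer | individuals pooled into the boat; 0 for controls |
| raw_gain          | numeric | dried mass minus boat tare, mg |
| split_denominator | integer | Motoda split used: 4, 8 or 16 |
| n_subsamples      | integer | number of 2-ml pipette subsamples pooled |
| is_control        | logical | TRUE for distilled-water control boats |

## lengths.csv
| column      | type    | description |
|-------------|---------|-------------|
| sample_id   | string  | as above |
| taxon_name  | string  | |
| stage_tag   | string  | optional |
| length      | numeric | µm; prosome length for copepods, longest body extension otherwise |

## stations.csv
station_id, depth_m (positive, metres), habitat (coast/bank/trough).

## events.csv
event_id, calendar_date (ISO 8601); day_of_year is derived at load time.

## taxa.csv (packaged reference)
taxon_name, plankton_group (holoplankton/meroplankton/ichthyoplankton),
size_class (SMZ/LMZ), carbon_factor (mg C per mg DW), energy_factor
(J per mg DW), cross_class_flag (taxa spanning both size classes, always
assigned to LMZ).

## allometric_formulas.csv (packaged reference)
method_id, target_taxon, functional_form (power / log_linear / log_log /
fixed / power_scaled), coef_a, coef_b, scale_div, length_unit (mm/um),
mass_unit (mg/ug), note. Logarithms are base 10.
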