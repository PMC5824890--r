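# Station table column dictionary

Delimited text (comma default), UTF-8, one header row, `#` comment lines,
missing values as empty fields. One row per station; `station_id` must be
unique within a table.

| column                 | units    | required | meaning                                        |
|------------------------|----------|----------|------------------------------------------------|
| station_id             | —        | yes      | station label                                  |
| depth_m                | m        | yes      | water depth (> 0)                              |
| sampling_year          | year AD  | yes      | calendar year of sampling                      |
| d13c_toc / _sd         | per mil  | no       | bulk organic carbon delta-13C, 1-sigma         |
| d14c_toc / _sd         | per mil  | no       | bulk organic carbon Delta-14C, 1-sigma         |
| c14_age_toc_kyr / _sd_kyr | kyr   | no       | conventional bulk 14C age, 1-sigma             |
| csra_cal_age_kyr / _sd_kyr | kyr  | no       | calibrated compound-specific biomarker age     |
| transport_time_kyr / _sd_kyr | kyr | no      | published net transport time (cross-checks)    |
| surface_area_m2_g / _sd | m2/g    | no       | mineral specific surface area                  |
| loading_<pool> / _sd   | per m2   | no       | surface-area-normalized pool loading, 1-sigma  |

Any `*_sd` column must be non-negative where present. Unknown columns are
carried through untouched.
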