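# Laptev Sea transect station table: radiocarbon data for bulk organic
# carbon and long-chain fatty acids, with deduced net transport times.
# Columns: see inst/extdata/station_columns.md. Missing values are empty.
station_id,depth_m,sampling_year,d14c_toc,d14c_toc_sd,c14_age_toc_kyr,c14_age_toc_sd_kyr,csra_cal_age_kyr,csra_cal_age_sd_kyr,transport_time_kyr,transport_time_sd_kyr
SW-06,92,2014,-364,2,3.57,0.02,9.99,0.34,3.56,0.32
SW-14,64,2014,-314,2,2.97,0.02,8.63,0.42,2.48,0.23
SW-23,56,2014,-333,2,3.19,0.02,8.47,0.16,2.17,0.18
YS-4,50,2008,-437,3,4.56,0.09,,,1.93,0.17
SW-24,46,2014,-284,2,2.62,0.02,9.67,0.23,1.78,0.16
YS-6,32,2008,-465,3,4.97,0.09,8.86,0.15,1.23,0.11
YS-9,23,2008,-415,6,4.25,0.09,7.33,0.07,0.89,0.08
YS-13,19,2008,-543,2,6.23,0.09,,,0.74,0.07
YS-14,7,2008,-504,2,5.58,0.09,,,0.27,0.03
TB-46,6,2008,-436,2,4.54,0.06,7.10,0.19,0.23,0.02
N-8,3.8,2008,,,,,6.30,0.16,,
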