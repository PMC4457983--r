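key,value
packets_captured,33939441
packets_lost,160269
adhoc_adl_total,1373
rbi_adl_correct,1264
car_adl_correct,1305
baseline_datasets_total,18214
nb_datasets_correct,5032
rf_datasets_correct,13971
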