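adl,nb_sensitivity,nb_specificity,rf_sensitivity,rf_specificity,rbi_sensitivity,rbi_specificity,car_sensitivity,car_specificity
sleeping,91.85,40.99,98.08,84.71,93.64,85.77,95.95,95.58
grooming,27.03,96.67,55.58,99.62,94.07,96.98,97.78,98.91
toileting,23.95,96.92,52.53,99.61,94.79,91.54,96.09,98.23
getting_ready_for_bed,9.53,98.52,43.03,99.86,92.38,94.48,95.24,98.39
cooking,26.88,98.83,47.28,99.92,84.29,90.92,91.43,98.23
eating,1.34,99.40,47.35,99.97,87.78,94.83,90.00,98.85
watching_tv,18.41,95.31,85.36,93.81,93.17,90.63,95.96,98.28
seated_activity,12.90,98.25,53.67,99.05,90.06,94.98,92.40,98.92
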