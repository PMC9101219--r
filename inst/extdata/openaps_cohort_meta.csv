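key,value
total_days,46070
n_individuals,122
reported_average_days,377
average_mean_glucose,139
average_sd_glucose,49.8
n_male,50
n_female,28
n_gender_missing,44
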