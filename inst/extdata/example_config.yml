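# freezekin pipeline configuration (all keys optional)
gyro_cutoff_hz: 3
accel_cutoff_hz: 10
filter_order: 2
ts_ho_threshold_dps: 30
n_central_strides: 10
gpqi_variant: as_printed
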