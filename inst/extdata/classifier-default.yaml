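config_version: 1
line_length_ratio_min: 2.0
rms_ratio_min: 1.8
sample_entropy_max: 0.55
spectral_concentration_min: 0.45
xcorr_max_min: 0.5
channel_quorum: 2
background_bins: 60
background_min_bins: 6
fallback_line_length: 2500.0
fallback_rms: 12.0
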