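threshold,n_events,detected,fp_events
90,13,12,62
50,18,18,139
10,35,28,324
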