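arm,timepoint_months,n_drusen
injected,0,25
injected,3,21
injected,6,23
injected,9,25
injected,12,32
uninjected,0,27
uninjected,3,NA
uninjected,6,NA
uninjected,9,41
uninjected,12,48
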