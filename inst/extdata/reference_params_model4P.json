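{"variant":"4P","seed":929,"generator":"make_reference_parameters","jitter":0.1,"draws":1,"screen":{"simulates":true,"pakt_induced":true,"ps6k1_induced":true,"mlst8_overshoot":true,"sin1_scan_biphasic":true,"pakt_scan_monotone":true}}
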