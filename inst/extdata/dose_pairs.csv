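input_eps,detected_eps
16,15
34,30
78,60
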