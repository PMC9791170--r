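detected_eps,slope
15,0.063
30,0.058
60,0.054
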