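4 3 1
# ALL-B ALL-T AML
0 1 2 0
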