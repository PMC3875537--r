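sample_id	class
s1	ALL-B
s2	ALL-T
s3	AML
s4	ALL-B
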