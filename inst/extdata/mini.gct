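#1.2
3	4
Name	Description	s1	s2	s3	s4
gA	first probe	120	3400	150	980
gB	second probe	16000	210	445	870
gC	third probe	101	15999	2500	640
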