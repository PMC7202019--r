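bin	validated	attempted	detected_novel	detected_known	detected_ref
≥1,000	32	44	460	227	465
500-999	16	41	186	43	90
250-499	13	40	320	28	67
100-249	6	36	876	34	77
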