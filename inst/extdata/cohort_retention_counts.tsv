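class	n_detected	n_after_mapq	n_after_reads
reference	1050	974	699
known_nonref	432	430	332
novel_nonref	155696	127976	1842
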