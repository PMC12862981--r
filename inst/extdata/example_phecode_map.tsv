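icd	phecode	label	excl_phecodes
E100	1.0	Simulated phenotype 1	0.50-1.50
E110	1.0	Simulated phenotype 1	0.50-1.50
E120	1.0	Simulated phenotype 1	0.50-1.50
E130	1.0	Simulated phenotype 1	0.50-1.50
C141	2.0	Simulated phenotype 2	1.50-2.50
C151	2.0	Simulated phenotype 2	1.50-2.50
C161	2.0	Simulated phenotype 2	1.50-2.50
C171	2.0	Simulated phenotype 2	1.50-2.50
I182	3.0	Simulated phenotype 3	2.50-3.50
I192	3.0	Simulated phenotype 3	2.50-3.50
I202	3.0	Simulated phenotype 3	2.50-3.50
I212	3.0	Simulated phenotype 3	2.50-3.50
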