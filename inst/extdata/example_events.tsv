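patient_id	code	date
P00003	E120	2009-04-27
P00007	E110	2009-10-27
P00008	E100	2009-05-28
P00011	E100	2009-05-27
P00013	E110	2009-09-08
P00025	E120	2009-07-06
P00030	E120	2009-02-17
P00014	E120	2010-07-04
P00022	E120	2010-04-18
P00002	C151	2009-03-28
P00003	C151	2009-10-04
P00004	C171	2009-08-13
P00013	C151	2009-06-22
P00018	C161	2009-01-18
P00020	C151	2009-07-31
P00022	C141	2009-06-09
P00023	C151	2009-12-01
P00024	C161	2009-05-15
P00030	C171	2009-06-03
P00001	C151	2010-04-22
P00005	C151	2010-12-16
P00006	C141	2010-07-28
P00009	C141	2010-04-27
P00015	C141	2010-04-04
P00010	I192	2009-09-11
P00012	I192	2009-06-19
P00016	I202	2009-01-31
P00021	I212	2009-08-29
P00028	I192	2009-07-03
P00001	I202	2010-08-10
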