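patient_id	modality	code	count
P00001	ICD	C141	3
P00001	ICD	C171	1
P00001	ICD	G769	1
P00001	ICD	I192	2
P00001	ICD	I202	1
P00001	ICD	P879	1
P00001	MED	MED0001	1
P00001	MED	MED0004	1
P00001	PROC	PROC0006	8
P00001	PROC	PROC0008	1
P00002	ICD	C141	5
P00002	ICD	D119	1
P00002	ICD	E100	1
P00002	ICD	E130	1
P00002	ICD	G769	1
P00002	MED	MED0005	2
P00002	MED	MED0007	1
P00002	PROC	PROC0006	3
P00003	ICD	C141	5
P00003	ICD	D119	1
P00003	ICD	E110	1
P00003	ICD	E130	3
P00003	ICD	I129	1
P00003	ICD	S549	1
P00003	MED	MED0004	2
P00003	PROC	PROC0006	1
P00004	ICD	C141	3
P00004	ICD	C171	2
P00004	MED	MED0004	1
P00004	PROC	PROC0006	2
P00005	ICD	C141	1
P00005	PROC	PROC0006	1
P00006	ICD	C141	5
P00006	ICD	C171	2
P00006	ICD	E919	1
P00006	ICD	I202	1
P00006	PROC	PROC0006	3
P00006	PROC	PROC0008	1
P00006	PROC	PROC0009	1
P00007	ICD	D119	2
P00007	ICD	E100	4
P00007	ICD	E130	3
P00007	ICD	I129	2
P00007	MED	MED0002	1
P00007	PROC	PROC0003	1
P00008	ICD	D119	4
P00008	ICD	E100	2
P00008	ICD	E130	3
P00008	ICD	I129	1
P00008	ICD	S549	1
P00008	MED	MED0002	5
P00008	MED	MED0004	2
P00008	MED	MED0007	1
P00008	MED	MED0012	2
P00008	PROC	PROC0003	5
P00009	ICD	C141	4
P00009	ICD	C151	1
P00009	ICD	C171	1
P00009	MED	MED0004	3
P00009	MED	MED0005	1
P00009	PROC	PROC0006	3
P00010	ICD	A389	2
P00010	ICD	I192	3
P00010	ICD	I202	7
P00010	ICD	L679	1
P00010	MED	MED0001	2
P00010	MED	MED0004	1
P00010	MED	MED0006	2
P00010	MED	MED0010	1
P00010	PROC	PROC0005	1
P00010	PROC	PROC0008	4
P00010	PROC	PROC0009	1
P00011	ICD	D119	1
P00011	ICD	I129	1
P00011	MED	MED0004	1
P00011	PROC	PROC0002	1
P00011	PROC	PROC0003	2
P00012	ICD	I192	1
P00012	ICD	I202	8
P00012	MED	MED0010	2
P00012	PROC	PROC0003	1
P00012	PROC	PROC0008	3
P00013	ICD	C141	1
P00013	ICD	C171	1
P00013	PROC	PROC0002	1
P00014	ICD	C141	1
P00014	ICD	C171	1
P00014	ICD	D119	1
P00014	ICD	E100	1
P00014	ICD	E110	2
P00014	ICD	E130	1
P00014	MED	MED0012	2
P00014	PROC	PROC0002	1
P00014	PROC	PROC0003	5
P00015	ICD	C141	2
P00016	ICD	I202	1
P00016	ICD	I212	1
P00016	MED	MED0004	1
P00016	MED	MED0006	2
P00016	PROC	PROC0005	2
P00016	PROC	PROC0008	1
P00017	ICD	C141	1
P00017	ICD	C171	1
P00017	ICD	E110	1
P00017	ICD	G769	1
P00017	MED	MED0004	1
P00017	MED	MED0005	1
P00017	MED	MED0010	1
P00017	PROC	PROC0006	2
P00018	ICD	C141	3
P00018	ICD	C171	1
P00018	ICD	G769	1
P00018	MED	MED0004	2
P00018	MED	MED0005	1
P00018	PROC	PROC0001	1
P00018	PROC	PROC0006	3
P00018	PROC	PROC0008	1
P00019	ICD	C141	3
P00019	ICD	C171	3
P00019	ICD	J309	1
P00019	MED	MED0004	3
P00019	PROC	PROC0004	1
P00019	PROC	PROC0006	1
P00020	ICD	A389	1
P00020	ICD	C141	3
P00020	MED	MED0004	2
P00020	PROC	PROC0006	1
P00020	PROC	PROC0011	1
P00021	ICD	I192	2
P00021	ICD	I202	1
P00021	ICD	L679	1
P00021	MED	MED0006	1
P00021	PROC	PROC0005	1
P00022	ICD	C141	2
P00022	ICD	E110	1
P00022	ICD	E130	3
P00022	MED	MED0004	1
P00022	PROC	PROC0006	2
P00023	ICD	C171	1
P00023	ICD	E919	1
P00023	MED	MED0004	1
P00024	ICD	C141	3
P00024	PROC	PROC0006	2
P00024	PROC	PROC0010	1
P00025	ICD	D119	3
P00025	ICD	E100	2
P00025	MED	MED0002	1
P00025	MED	MED0012	2
P00025	PROC	PROC0002	1
P00025	PROC	PROC0003	3
P00026	ICD	E100	1
P00026	MED	MED0002	1
P00027	MED	MED0002	2
P00027	PROC	PROC0003	3
P00028	ICD	I192	1
P00028	ICD	I202	4
P00028	ICD	L679	1
P00028	MED	MED0006	3
P00028	MED	MED0010	2
P00028	PROC	PROC0009	1
P00029	ICD	D119	2
P00029	ICD	E100	3
P00029	ICD	E110	2
P00029	ICD	E130	4
P00029	MED	MED0002	2
P00029	MED	MED0012	2
P00029	PROC	PROC0003	1
P00030	ICD	E100	1
P00030	ICD	I129	1
P00030	MED	MED0002	1
P00030	MED	MED0004	1
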