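patient_id	baseline_date
P00001	2010-01-01
P00002	2010-01-01
P00003	2010-01-01
P00004	2010-01-01
P00005	2010-01-01
P00006	2010-01-01
P00007	2010-01-01
P00008	2010-01-01
P00009	2010-01-01
P00010	2010-01-01
P00011	2010-01-01
P00012	2010-01-01
P00013	2010-01-01
P00014	2010-01-01
P00015	2010-01-01
P00016	2010-01-01
P00017	2010-01-01
P00018	2010-01-01
P00019	2010-01-01
P00020	2010-01-01
P00021	2010-01-01
P00022	2010-01-01
P00023	2010-01-01
P00024	2010-01-01
P00025	2010-01-01
P00026	2010-01-01
P00027	2010-01-01
P00028	2010-01-01
P00029	2010-01-01
P00030	2010-01-01
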