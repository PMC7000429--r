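variable	control_mean	control_sd	control_n	patient_mean	patient_sd	patient_n
age	65.1	5.0	14	68.3	9.8	13
education	10.4	4.1	14	8.5	4.1	13
mmse	28.4	2.2	14	23.5	2.3	13
moca	27.1	2.3	14	14.7	3.8	13
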