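patient_id	cfdna_t0_ng	cfdna_t1_ng
HROC520	46.8	41.4
HROC528	16.4	53.1
HROC534	21.9	35.3
HROC535	53.4	32.0
HROC536	19.6	53.2
HROC539	19.6	49.8
HROC540	44.7	69.3
HROC544	34.5	366.0
HROC547	10.2	43.9
HROC554	56.7	21.2
HROC556	39.2	58.3
HROC558	45.5	48.2
HROC562	176.0	137.9
HROC566	18.6	5.25
HROC574	18.1	21.2
HROC586	6.4	19.9
HROC601	29.2	39.2
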