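father	family_size
MSSB	47
MSSH	68
SSP01	24
SSP02	27
SSP03	4
SSP04	10
SSP05	16
SSP06	13
SSP07	9
SSP08	17
SSP09	12
SSP10	9
SSP11	17
SSP12	86
SSP13	15
SSP14	10
SSP15	2
SSP16	13
SSP17	3
SSP18	8
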