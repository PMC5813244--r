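design	delta	alpha	n
discordant_twin	7	0.05	30
discordant_twin	8	0.05	25
discordant_twin	9	0.05	20
discordant_twin	10	0.05	17
discordant_twin	11	0.05	15
discordant_twin	12	0.05	13
discordant_twin	13	0.05	11
discordant_twin	14	0.05	10
discordant_twin	15	0.05	9
discordant_twin	7	1e-06	178
discordant_twin	8	1e-06	145
discordant_twin	9	1e-06	117
discordant_twin	10	1e-06	98
discordant_twin	11	1e-06	81
discordant_twin	12	1e-06	71
discordant_twin	13	1e-06	63
discordant_twin	14	1e-06	55
discordant_twin	15	1e-06	50
case_control	7	0.05	37
case_control	8	0.05	30
case_control	9	0.05	24
case_control	10	0.05	20
case_control	11	0.05	17
case_control	12	0.05	15
case_control	13	0.05	13
case_control	14	0.05	11
case_control	15	0.05	10
case_control	7	1e-06	211
case_control	8	1e-06	169
case_control	9	1e-06	137
case_control	10	1e-06	112
case_control	11	1e-06	96
case_control	12	1e-06	80
case_control	13	1e-06	70
case_control	14	1e-06	61
case_control	15	1e-06	54
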