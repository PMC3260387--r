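t_first_defib_mean	15
t_first_defib_sd	5
shock_interval_mean	145
shock_interval_sd	10
peri_shock_pause	8
cc_segment_mean	60
cc_segment_sd	8
cc_pause_mean	10
cc_pause_sd	3
vent_rate	0.5
t_iv	90
t_intubation	200
t_epi1	400
t_epi2	560
t_amiodarone	600
t_atropine	NA
cc_output	1.5
seed	102
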