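t_first_defib_mean	105
t_first_defib_sd	10
shock_interval_mean	140
shock_interval_sd	10
peri_shock_pause	10
cc_segment_mean	70
cc_segment_sd	8
cc_pause_mean	9
cc_pause_sd	3
vent_rate	1.5
t_iv	100
t_intubation	220
t_epi1	450
t_epi2	520
t_amiodarone	560
t_atropine	NA
cc_output	1.5
seed	105
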