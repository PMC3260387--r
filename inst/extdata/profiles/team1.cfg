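t_first_defib_mean	180
t_first_defib_sd	20
shock_interval_mean	230
shock_interval_sd	15
peri_shock_pause	10
cc_segment_mean	90
cc_segment_sd	10
cc_pause_mean	6
cc_pause_sd	2
vent_rate	1.1
t_iv	150
t_intubation	300
t_epi1	540
t_epi2	720
t_amiodarone	780
t_atropine	NA
cc_output	1.2
seed	101
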