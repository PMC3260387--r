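t_first_defib_mean	105
t_first_defib_sd	10
shock_interval_mean	190
shock_interval_sd	15
peri_shock_pause	20
cc_segment_mean	35
cc_segment_sd	5
cc_pause_mean	18
cc_pause_sd	4
vent_rate	1.3
t_iv	140
t_intubation	170
t_epi1	300
t_epi2	330
t_amiodarone	360
t_atropine	NA
cc_output	1.4
seed	103
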