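t_first_defib_mean	100
t_first_defib_sd	10
shock_interval_mean	165
shock_interval_sd	10
peri_shock_pause	6
cc_segment_mean	100
cc_segment_sd	10
cc_pause_mean	6
cc_pause_sd	2
vent_rate	0.3
t_iv	180
t_intubation	350
t_epi1	610
t_epi2	740
t_amiodarone	NA
t_atropine	NA
cc_output	1.8
seed	104
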