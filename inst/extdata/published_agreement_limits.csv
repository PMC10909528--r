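# Published cohort Bland-Altman limits of agreement (algorithm - PSG),
# as printed in the source study's agreement table (N = 71 nights).
variable,bias,loa_lower,loa_upper
sleep_interval_min,-21,-86,44
total_sleep_time_min,-32,-148,85
sleep_latency_min,23,-38,83
waso_min,10,-84,104
sleep_efficiency_pct,-7.2,-34,20
awakening_index_per_h,-1.1,-2.3,0.1
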