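analysis,cost_exp,qaly_exp,cost_ctrl,qaly_ctrl
base_case,43708.75,0.93,14063.87,0.66
assistance_program,27419.73,0.93,14063.87,0.66
partitioned_survival,58969.58,1.14,21537.60,0.65
io_treated,61448.48,1.43,14060.26,0.66
io_naive,51467.72,1.06,14060.26,0.66
negotiated_price,14411.14,0.93,14063.87,0.66
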