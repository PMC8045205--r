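# name=nirs-16fx-lem
label,metric_kind,volume_param,limit_gy_rbe,model,n_fractions
D20%,percent-volume,0.2,43.14,LEM,16
D10%,percent-volume,0.1,58.48,LEM,16
D5%,percent-volume,0.05,65.11,LEM,16
D0%,percent-volume,0,68.33,LEM,16
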