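# name=nirs-16fx
label,metric_kind,volume_param,limit_gy_rbe,model,n_fractions
D20%,percent-volume,0.2,28.8,MKM,16
D10%,percent-volume,0.1,46.4,MKM,16
D5%,percent-volume,0.05,56,MKM,16
D0%,percent-volume,0,60.8,MKM,16
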