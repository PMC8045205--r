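# name=cnao-16fx
label,metric_kind,volume_param,limit_gy_rbe,model,n_fractions
D10cc,absolute-volume,10,54,LEM,16
D5cc,absolute-volume,5,61,LEM,16
D1cc,absolute-volume,1,66,LEM,16
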