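# scheme=12
# id=12fx-scanning-protocol
mkm_dose_gy_rbe,lem_dose_gy_rbe
41.28,49
51.6,55.71
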