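# scheme=16
# id=16fx-published-anchors
mkm_dose_gy_rbe,lem_dose_gy_rbe
28.8,43.14
39.99,54
46.4,58.48
49.84,61
56,65.11
57.31,66
60.8,68.33
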