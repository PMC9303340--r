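patch_id,diameter_um
p01,21.4
p01,24.9
p01,27.8
p01,19.6
p01,30.2
p01,25.3
p02,14.1
p02,16.8
p02,15.9
p02,13.2
p02,18.4
p02,35.6
p03,38.9
p03,41.2
p03,33.5
p03,36.8
p03,44.1
p03,39.7
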