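# PGSE protocol description: gradient duration/separation in ms, b-values in
# s/mm^2, SNR at b = 0 (use .inf for noise-free synthesis)
delta: 20
Delta: 75
bmin: 100
bmax: 1500
n_b: 7
snr: 20
directions:
  - [1, 0, 0]
  - [0, 1, 0]
  - [0, 0, 1]
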