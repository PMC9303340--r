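# Microstructure grid: cell sizes L in um, intrinsic diffusivities D0 in
# um^2/ms; omega_halfwidth is the pooling half-width in grid steps
L_min: 11
L_max: 60
L_step: 1.5
D0_min: 0.20
D0_max: 2.40
D0_step: 0.05
omega_halfwidth: 2
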