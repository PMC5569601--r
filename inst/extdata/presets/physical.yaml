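# Physical and numerical constants shared by all presets.
# Units: aL [Pa s at 1 g/100 ml], bL [-], tauA [s/g], L [m], u [m/s],
# rho_w [g/ml], l0 [m], dz [m].
aL: 2.0
bL: 4.21
tauA: 5.0e+6
L: 2.85
u: 1.7e-4
rho_w: 1.0
l0: 0.025
dz: 5.0e-3
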