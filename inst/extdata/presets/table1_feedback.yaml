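# Fitted feedback-only parameters for eight glucose-drink conditions.
# Units: StomN0 [g], gamma0 [1/s], Amax [g/s], Ka [1/s].
# Condition a was fitted without the brake (pure exponential): Amax is
# infinite and Ka zero.  Conditions b-d, e-f and g-h share brake
# parameters within a source.  HP = high polymer (viscous) drink.
a: {StomN0: 15.03, gamma0: 1.20e-3, Amax: .inf, Ka: 0.0,    label: "15 g glucose"}
b: {StomN0: 20.82, gamma0: 9.23e-4, Amax: 7.0e-3, Ka: 9.0e-4, label: "20 g glucose"}
c: {StomN0: 54.33, gamma0: 9.23e-4, Amax: 7.0e-3, Ka: 9.0e-4, label: "50 g glucose"}
d: {StomN0: 98.95, gamma0: 9.23e-4, Amax: 7.0e-3, Ka: 9.0e-4, label: "100 g glucose"}
e: {StomN0: 24.74, gamma0: 9.22e-4, Amax: 1.0e-2, Ka: 1.7e-3, label: "24 g glucose, low polymer"}
f: {StomN0: 114.28, gamma0: 9.22e-4, Amax: 1.0e-2, Ka: 1.7e-3, label: "112.8 g glucose, low polymer"}
g: {StomN0: 23.98, gamma0: 8.98e-4, Amax: 1.0e-2, Ka: 4.2e-4, label: "24 g glucose, HP"}
h: {StomN0: 112.83, gamma0: 8.98e-4, Amax: 1.0e-2, Ka: 4.2e-4, label: "112.8 g glucose, HP"}
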