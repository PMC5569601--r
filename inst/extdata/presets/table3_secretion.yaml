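# Optimal secretion-model parameters for non-nutrient thickened meals,
# with emptying-rate hypothesis SEC_PLUS_C (gamma0 = msec*Ksec + C1).
# Units: msec [1/g], C1 [1/s], lambdaS [g/s per (Pa s)^b], b [-], Sb [g/s].
# upper/lower are mean +/- 2 sd from a 5000-iteration Monte-Carlo refit.
mean:  {msec: 2.5e-3,  C1: 6.58e-4, lambdaS: 1.8e-2,  b: 1.5, Sb: 1.8e-2}
upper: {msec: 1.74e-2, C1: 8.38e-4, lambdaS: 6.21e-2, b: 2.2, Sb: 2.8e-2}
lower: {msec: 3.27e-4, C1: 4.69e-4, lambdaS: 1.4e-3,  b: 0.2, Sb: 1.4e-3}
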