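# Optimal combined-model parameters for four liquid meals:
# LVN/HVN = low/high viscosity nutrient meal, LVC/HVC = low/high viscosity
# control (low nutrient) meal.  Hypothesis SEC_PLUS_C throughout.
# Units: Amax [g/s], msec [1/g], C1 [1/s], lambdaS [g/s (Pa s)^-b], b [-],
# Sb [g/s], Ka [1/s], mu0 [Pa s], liq0 [g], StomN0 [g].
# The meal compositions (mu0, liq0, StomN0) are package choices emulating
# the study meals: 500 ml drinks; nutrient meals ~80 g glucose-equivalent
# (323 kcal), controls ~16 g (64 kcal); high-viscosity meals at the top of
# the fitted rheology range (11 Pa s), low-viscosity near water-thin.
LVN: {Amax: 1.04e-2, msec: 3.66e-4, C1: 6.77e-4, lambdaS: 4.05e-2, b: 1.08,
      Sb: 5.7e-3,  Ka: 9.80e-3, mu0: 0.06, liq0: 500, StomN0: 80}
HVN: {Amax: 9.8e-3,  msec: 3.48e-4, C1: 4.74e-4, lambdaS: 6.17e-2, b: 0.40,
      Sb: 1.51e-2, Ka: 2.89e-4, mu0: 11,   liq0: 500, StomN0: 80}
LVC: {Amax: 1.00e-2, msec: 3.27e-4, C1: 4.69e-4, lambdaS: 6.21e-2, b: 0.67,
      Sb: 2.13e-2, Ka: 9.80e-3, mu0: 0.06, liq0: 500, StomN0: 16}
HVC: {Amax: 1.01e-2, msec: 3.27e-4, C1: 5.86e-4, lambdaS: 6.21e-2, b: 0.42,
      Sb: 2.34e-2, Ka: 2.89e-4, mu0: 11,   liq0: 500, StomN0: 16}
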