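# Final population-model parameters (variance-scale omega/sigma)
theta_cl: 8.59      # L/h at 70 kg
theta_v: 294.0      # L at 70 kg
theta_oxc: 1.16     # clearance multiplier under oxcarbazepine
power_cl: 0.75      # allometric exponent, clearance
power_v: 1.0        # allometric exponent, volume
w_std: 70.0         # reference weight, kg
ka_fixed: 0.485     # absorption rate constant, 1/h (not estimated)
omega_cl: 0.175     # IIV variance on CL/F (eta_V dropped)
error_kind: additive
sigma1: 1.913       # additive residual variance, (ng/ml)^2
scale: variance
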