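# Set-A model parameters: full-strength D-ring carbonyl ... His290 hydrogen
# bond. Frozen output of the calibration procedure described in the methods
# vignette (targets: relaxed S1 barrier 1.6 kcal/mol, tau_A 2.24 ps,
# quantum yield ~0.15, hop-geometry median near 90 deg).
# Units: kcal/mol, Angstrom, degrees, amu, ps^-1, K.
E_vert: 55.0
V6_S1: 46.0
V6_S0: 57.05
V5: 8.0
chi: 3.0
theta6_CI: 90.0
w0: 0.80
sigma_w: 12.0
D_hb: 4.0
a_hb: 2.0
r0_hb: 1.9
lambda_hb: 7.5567830637
theta_off: 8.0
w_cw: 30.0
k_cage: 0.5
r_cage: 3.5
h_strain: 3.8
theta_strain: 112.7
sigma_strain: 8.0
s6: 1.0
I6: 110.0
I5: 60.0
m_r: 12.0
gamma_s1: 3.0
T_s1: 750.0
gamma_s0: 50.0
T: 300.0
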