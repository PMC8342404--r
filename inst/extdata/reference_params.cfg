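D_c = 0.0028800000000000002
D_F = 9.9999999999999995e-08
chi_F = 0.002
k_c = 4.0000000000000001e-13
r_F = 0.92400000000000004
r_F_max = 2
k_rho = 7.5937500000000001e-08
k_rho_max = 10
a_c_I = 1e-08
a_c_II = 200000000
a_c_III = 1e-08
a_c_IV = 1.0000000000000001e-09
eta_I = 2
eta_II = 0.5
k_F = 10800000
kappa_F = 9.9999999999999995e-07
q = -0.41506929253841879
delta_c = 0.00050000000000000001
delta_N = 0.02
delta_M = 0.059999999999999998
delta_rho = 6.0000000000000002e-06
zeta = 400
rho_t = 1.0900000000000001
mu = 100
E = 210
xi = 0.043999999999999997
R = 0.995
N_bar = 10000
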