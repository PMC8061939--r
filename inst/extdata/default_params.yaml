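# Default parameter set of the ischaemic-hepatitis model (rates per day).
A_norm: 1.6e+9
rho: 1.43
k: 1.43
r: 1.0
eta: 6.381
delta_Z: 5.0
H_max: 1.6e+11
theta: 5.0
delta_S: 0.92
delta_L: 0.35
delta_D: 0.459
beta_S: 20000.0
beta_L: 9000.0
beta_D: 200000.0
S_min: 12.0
L_min: 9.0
D_min: 120.0
D_max: 30000.0
O0: 0.5
epsilon: 20.0
tau_hours: .inf
c_reperfusion: 0.0
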