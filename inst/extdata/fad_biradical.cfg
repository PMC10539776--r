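# Default model parameters for the flavin-adenine biradical of FAD.
# Units: g factors dimensionless; hyperfine couplings and J0 in mT;
# alpha as printed (see exchange conventions); D in cm^2/s; G in s^-2;
# times in s; rates in s^-1.
ga = 2.0034
gb = 2.0035
A = -0.7
A_add = 1.67
n_add = 4
J0 = -2.3e8
alpha = 0.214
convention = decay_length_from_contact
r_contact = 0.49
lambda = 0.0214
D = 2e-7
G = 6.1e17
tau_u = 1e-12
tau_rot = 8e-10
kp = 2e10
ks = 1e5
additional_nuclei = quantum
J_cap = 1e4
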