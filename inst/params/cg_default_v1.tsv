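# swishmc coarse-grained model parameters, version 1
# key	value
param_version	1
temperature	300
dielectric	78.5
debye_length	9.6
s_apolar	0.03
cutoff_exposure	6.5
n_max	8
hardcore	1.8
eps_ca	0.05
sigma_ca	4.2
eps_sc_h	0.12
eps_sc_p	0.06
sigma_sc	4.5
helix_phi	-57
helix_psi	-47
helix_width	25
helix_depth	3.0
ext_phi	-135
ext_psi	135
ext_width	35
ext_depth	1.4
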