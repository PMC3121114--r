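rho:
- 0.002
- 0.0025
- 0.001
k_s:
- .na.real
- 5.0
- 6.0
k_1:
- .na.real
- 0.1
- 0.1
k_d:
- 0.5
- 0.4
- 0.3
r:
- 0.5
- 0.5
- 0.5
eta:
- 1.0
- 1.0
- 1.0
b:
- 1.0
- 0.0
- 0.0
h: 1.0
u0: 50.0
K: 0.3
beta: 1.0e-06
label: xlnr-canonical+feedback
S1: 3
S2: 2
k_RL: 1.0
k_AL: 1.0
k_ls: 1.0
tau: 1.0
C_A: 0.0
k_A: 0.0
creA_binary: yes
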