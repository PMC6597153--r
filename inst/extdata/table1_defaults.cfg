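# default forest-savanna calibration (average seasonality and soils)
r_S = 0.09
r_F = 0.2
k_RS = 0.005
k_RF = 0.003
a_RS = 0.25
a_RF = 1.54
m_So = 0.023
m_Fo = 0.041
a_MS = 0
a_MF = -2.15
k_MS = 0.008
k_MF = 0.008
Q0 = 0.04
h = 0.85
tau = 2.7
n_fire = 4
Y_c0 = 0.56
k_c = -0.000143
b = 0.46
c_def = 0.092
k_C = 0.0015
D_S = 0.2
D_F = 0.1
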