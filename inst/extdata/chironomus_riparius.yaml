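# DEB parameters of the Chironomus riparius hax model at T_ref = 293.15 K.
# Units: energies J, volumes cm^3, lengths cm, times d, temperatures K.
# kap_R is not part of the published set (conventional DEB default).
p_Am: 203.0        # J/(d cm^2), surface-specific max assimilation (x s_M)
v: 0.007           # cm/d, energy conductance (x s_M)
kap: 0.44          # allocation fraction to soma
p_M: 145.1         # J/(d cm^3), volume-specific somatic maintenance
k_J: 0.036         # 1/d, maturity maintenance rate coefficient
E_G: 4018          # J/cm^3, specific cost for structure
E_Hb: 0.003        # J, maturity at birth
E_Hp: 0.277        # J, maturity at puberty
E_He: 1.072        # J, maturity at emergence
E_Rj: 5323         # J/cm^3, reproduction buffer density at pupation
kap_V: 1.1e-06     # conversion efficiency structure -> reserve at pupation
kap_R: 0.95        # reproduction efficiency (conventional default)
T_A: 6420          # K, Arrhenius temperature
T_AH: 18250        # K, Arrhenius temperature, upper boundary
T_H: 309.9         # K, upper boundary of the tolerance range
T_ref: 293.15      # K, reference temperature (20 degC)
del_M1: 0.083      # shape coefficient, alive individuals
del_M2: 0.067      # shape coefficient, dead individuals
s_1: 2.48          # molt constant, 1st molt
s_2: 2.48          # molt constant, 2nd molt
h_b: 0.02          # 1/d, background hazard rate
k_starv: 3.09      # 1/d, starvation killing rate
p_Amm: 172.3       # J/(d cm^2), male surface-specific max assimilation
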