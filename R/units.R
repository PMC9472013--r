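# Internal unit conventions.
#
# All curve-level quantities are carried in the units the instrument and the
# literature use: piezo height z, deflection d and indentation delta in um,
# time in s, force in nN, moduli in Pa, dissipated energy in fJ.
# The only non-trivial conversion factors are collected here so they appear
# exactly once.

# k [N/m] * d [um] -> force [nN]:  1 N/m * 1 um = 1e-6 N = 1e3 nN
.K_UM_TO_NN <- 1e3

# Hertz prefactor: with E in Pa, R and delta in um,
#   F [N]  = (4/3) * E/(1-nu^2) * sqrt(R_m) * delta_m^(3/2)
#          = (4/3) * E/(1-nu^2) * sqrt(R_um)*1e-3 * delta_um^(3/2)*1e-9
# so F [nN] = (4/3) * E/(1-nu^2) * sqrt(R_um) * delta_um^(3/2) * 1e-3
.HERTZ_NN <- 1e-3

# 1 nN * 1 um = 1e-15 J = 1 fJ: force-indentation areas are already in fJ.
.NN_UM_TO_FJ <- 1

# Boltzmann constant [J/K]
.K_BOLTZMANN <- 1.380649e-23
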