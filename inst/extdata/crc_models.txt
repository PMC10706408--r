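# cellkin model library: consecutive-reaction-chain recruitment models
# and companions. One model per block:
#   [name]
#   expression over t and the parameters   (or: builtin: <id>)
#   parameter = initial [lower, upper]
#
# S_m(t) below is the occupancy of the final bound state of the chain
# S0 -> S1 -> ... -> Sm -> removed, written out explicitly.

[crc1_no_removal]
B + A*(1 - exp(-k1*t))
A = 1 [0, 1e6]
k1 = 0.05 [1e-8, 10]
B = 0

[crc1]
B + A*( f*( k1*( exp(-k1*t)/(kr-k1) + exp(-kr*t)/(k1-kr) ) ) + (1-f)*(1 - exp(-k1*t)) )
A = 1 [0, 1e6]
k1 = 0.05 [1e-8, 10]
kr = 0.005 [1e-8, 10]
f = 0.8 [0, 1]
B = 0

[crc2]
B + A*( f*( k1*k2*( exp(-k1*t)/((k2-k1)*(kr-k1)) + exp(-k2*t)/((k1-k2)*(kr-k2)) + exp(-kr*t)/((k1-kr)*(k2-kr)) ) ) + (1-f)*( 1 + k1*k2*( exp(-k1*t)/((k2-k1)*(-k1)) + exp(-k2*t)/((k1-k2)*(-k2)) ) ) )
A = 1 [0, 1e6]
k1 = 0.1 [1e-8, 10]
k2 = 0.02 [1e-8, 10]
kr = 0.005 [1e-8, 10]
f = 0.8 [0, 1]
B = 0

[crc3]
builtin: crc3

[expdecay]
C + A*exp(-k*t)
A = 1 [-1e6, 1e6]
k = 0.01 [1e-8, 10]
C = 0

[frap_single]
Finf - (Finf - F0)*exp(-k*t)
F0 = 0.2
Finf = 1 [0, 10]
k = 0.05 [1e-8, 10]

[frap_double]
builtin: frap2
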