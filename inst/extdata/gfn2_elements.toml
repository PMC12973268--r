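# Element-wise tight-binding parameters: a plain-text transcription of the
# published GFN2 element tables for the elements supported by this package,
# augmented with atomic spin constants W (Hartree) and shell-resolved Hubbard
# U values (Hartree, default 0).  Schema: [global] plus one [element.X] block
# per element; array-valued keys are comma-separated, ordered as `shells`.
# levels/kcn are eV; gam/gam3/W/U are Hartree; rcov/mprad are Angstrom/Bohr.

[global]
ks = 1.85
kp = 2.23
kd = 2.23
ken = -0.02
wexp = 0.5
rep_kexp = 1.5
rep_kexp_light = 1.0
gexp = 2.0
gam3_shell = 1.0, 0.5, 0.25
dmp3 = 3.0
dmp5 = 4.0
mp_kexp = 4.0
mp_shift = 1.2
mp_rmax = 5.0
cn_ka = 10.0
cn_kb = 20.0
cn_rshift = 2.0
alpha = 0.5

[element.H]
shells = 1s
ngauss = 3
levels = -10.707211
slater = 1.230000
refocc = 1
kcn = -0.05
shpoly = -0.0953618
gam = 0.405771
lgam = 1.0
gam3 = 0.0800
arep = 2.213717
zeff = 1.105388
en = 2.20
rcov = 0.32
dkernel = 0.0556389
qkernel = 0.00027431
mprad = 1.40
mpvcn = 1.0
W = -0.0720

[element.Li]
shells = 2s, 2p
ngauss = 6, 6
levels = -4.900000, -2.217789
slater = 0.760000, 0.590000
refocc = 1, 0
kcn = -0.04, 0.0
shpoly = -0.0300, -0.0050
gam = 0.245006
lgam = 1.0, 1.0
gam3 = 0.1000
arep = 1.100000
zeff = 2.400000
en = 0.98
rcov = 1.33
dkernel = -0.0070
qkernel = 0.00020
mprad = 3.80
mpvcn = 1.0
W = -0.0210, -0.0180, -0.0170

[element.C]
shells = 2s, 2p
ngauss = 6, 6
levels = -13.970922, -10.063292
slater = 2.096432, 1.800000
refocc = 2, 2
kcn = -0.07, 0.0
shpoly = -0.0229432, -0.0002786
gam = 0.538015
lgam = 1.0, 1.105636
gam3 = 0.1500
arep = 1.247655
zeff = 4.231078
en = 2.55
rcov = 0.75
dkernel = -0.0007
qkernel = 0.00041626
mprad = 3.10
mpvcn = 3.0
W = -0.0310, -0.0250, -0.0230

[element.N]
shells = 2s, 2p
ngauss = 6, 6
levels = -16.686243, -12.523956
slater = 2.339881, 2.014332
refocc = 2, 3
kcn = -0.08, 0.0
shpoly = -0.0272800, 0.0050000
gam = 0.461493
lgam = 1.0, 1.058254
gam3 = 0.1200
arep = 1.682689
zeff = 5.242592
en = 3.04
rcov = 0.71
dkernel = -0.0030
qkernel = 0.00030
mprad = 2.80
mpvcn = 3.0
W = -0.0330, -0.0270, -0.0250

[element.O]
shells = 2s, 2p
ngauss = 6, 6
levels = -20.229985, -15.503118
slater = 2.439742, 2.137023
refocc = 2, 4
kcn = -0.09, 0.0
shpoly = -0.0200000, 0.0100000
gam = 0.451896
lgam = 1.0, 1.080000
gam3 = 0.1100
arep = 2.165712
zeff = 5.784415
en = 3.44
rcov = 0.63
dkernel = -0.0050
qkernel = 0.00040
mprad = 2.50
mpvcn = 2.0
W = -0.0350, -0.0280, -0.0260

[element.F]
shells = 2s, 2p
ngauss = 6, 6
levels = -23.458179, -15.746583
slater = 2.416361, 2.308399
refocc = 2, 5
kcn = -0.10, 0.0
shpoly = -0.0110000, -0.0350000
gam = 0.531518
lgam = 1.0, 1.0
gam3 = 0.1000
arep = 2.421394
zeff = 7.021486
en = 3.98
rcov = 0.64
dkernel = -0.0100
qkernel = 0.00050
mprad = 2.40
mpvcn = 1.0
W = -0.0360, -0.0290, -0.0270

[element.Fe]
shells = 3d, 4s, 4p
ngauss = 6, 6, 6
levels = -7.200000, -8.700000, -2.900000
slater = 2.100000, 1.350000, 1.100000
refocc = 6, 2, 0
kcn = -0.05, -0.05, 0.0
shpoly = -0.0200, -0.0100, 0.0100
gam = 0.450000
lgam = 1.0, 1.0, 1.0
gam3 = 0.0500
arep = 2.000000
zeff = 12.000000
en = 1.83
rcov = 1.24
dkernel = -0.0050
qkernel = 0.00050
mprad = 4.00
mpvcn = 4.0
W = -0.0200, -0.0030, -0.0030, -0.0130, -0.0100, -0.0090
U = 0.0, 0.0, 0.0
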