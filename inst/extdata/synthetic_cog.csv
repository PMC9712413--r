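# synthetic_cog.csv (version 1)
# SYNTHETIC approximate conformation-specific centres of gravity (ppm)
# of chemical-shift distributions within helical and extended
# conformations, per residue type and nucleus.  Stand-in for a
# database-derived table; replace with your own for production use.
residue,nucleus,helix,extended
A,H,7.99,8.54
A,N,122.3,125.8
A,CA,55,50
A,CB,18,23
R,H,7.98,8.53
R,N,119,122.5
R,CA,58.6,54.2
R,CB,30.1,33.3
N,H,8.15,8.7
N,N,117.2,120.7
N,CA,55.7,51.3
N,CB,38.1,41.3
D,H,8.09,8.64
D,N,118.9,122.4
D,CA,56.8,52.4
D,CB,40.3,43.5
C,H,8.07,8.62
C,N,117.3,120.8
C,CA,60.8,56.4
C,CB,27.2,30.4
E,H,8.17,8.72
E,N,118.7,122.2
E,CA,59.2,54.8
E,CB,29.1,32.3
Q,H,8.07,8.62
Q,N,118.3,121.8
Q,CA,58.3,53.9
Q,CB,28.6,31.8
G,H,8.08,8.63
G,N,107.3,110.8
G,CA,46.3,44.1
H,H,8.17,8.72
H,N,116.7,120.2
H,CA,57.6,53.2
H,CB,28.2,31.4
I,H,7.75,8.3
I,N,118.9,122.4
I,CA,63.7,59.3
I,CB,38,41.2
L,H,7.91,8.46
L,N,120.3,123.8
L,CA,57.7,53.3
L,CB,41.6,44.8
K,H,8.04,8.59
K,N,118.9,122.4
K,CA,58.8,54.4
K,CB,32.3,35.5
M,H,8.03,8.58
M,N,118.1,121.6
M,CA,58,53.6
M,CB,32.1,35.3
F,H,8.05,8.6
F,N,118.8,122.3
F,CA,60.3,55.9
F,CB,38.8,42
P,N,135.9,139.4
P,CA,65.9,61.5
P,CB,31.3,34.5
S,H,8.06,8.61
S,N,114.2,117.7
S,CA,60.9,56.5
S,CB,63,66.2
T,H,7.9,8.45
T,N,112.1,115.6
T,CA,64.5,60.1
T,CB,69,72.2
W,H,8,8.55
W,N,119.8,123.3
W,CA,60.1,55.7
W,CB,28.8,32
Y,H,7.87,8.42
Y,N,118.8,122.3
Y,CA,60.5,56.1
Y,CB,38,41.2
V,H,7.78,8.33
V,N,118.8,122.3
V,CA,64.9,60.5
V,CB,31.3,34.5
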