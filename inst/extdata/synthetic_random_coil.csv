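# synthetic_random_coil.csv (version 1)
# SYNTHETIC approximate neighbour-corrected random-coil shifts (ppm).
# Stand-in for a published random-coil reference set; replace with
# your preferred table (same schema) for production use.
# kind: base = random-coil shift of 'residue'; prev/next = additive
# correction exerted by a flanking residue of type 'residue'.
kind,residue,nucleus,value
base,A,H,8.24
base,R,H,8.23
base,N,H,8.4
base,D,H,8.34
base,C,H,8.32
base,E,H,8.42
base,Q,H,8.32
base,G,H,8.33
base,H,H,8.42
base,I,H,8
base,L,H,8.16
base,K,H,8.29
base,M,H,8.28
base,F,H,8.3
base,S,H,8.31
base,T,H,8.15
base,W,H,8.25
base,Y,H,8.12
base,V,H,8.03
base,A,N,123.8
base,R,N,120.5
base,N,N,118.7
base,D,N,120.4
base,C,N,118.8
base,E,N,120.2
base,Q,N,119.8
base,G,N,108.8
base,H,N,118.2
base,I,N,120.4
base,L,N,121.8
base,K,N,120.4
base,M,N,119.6
base,F,N,120.3
base,P,N,137.4
base,S,N,115.7
base,T,N,113.6
base,W,N,121.3
base,Y,N,120.3
base,V,N,120.3
base,A,CA,52.5
base,R,CA,56
base,N,CA,53.1
base,D,CA,54.2
base,C,CA,58.2
base,E,CA,56.6
base,Q,CA,55.7
base,G,CA,45.1
base,H,CA,55
base,I,CA,61.1
base,L,CA,55.1
base,K,CA,56.2
base,M,CA,55.4
base,F,CA,57.7
base,P,CA,63.3
base,S,CA,58.3
base,T,CA,61.9
base,W,CA,57.5
base,Y,CA,57.9
base,V,CA,62.3
base,A,CB,19.1
base,R,CB,30.9
base,N,CB,38.9
base,D,CB,41.1
base,C,CB,28
base,E,CB,29.9
base,Q,CB,29.4
base,H,CB,29
base,I,CB,38.8
base,L,CB,42.4
base,K,CB,33.1
base,M,CB,32.9
base,F,CB,39.6
base,P,CB,32.1
base,S,CB,63.8
base,T,CB,69.8
base,W,CB,29.6
base,Y,CB,38.8
base,V,CB,32.1
prev,G,H,-0.05
prev,G,N,-0.5
prev,G,CA,-0.1
next,G,H,0.02
next,G,N,0.4
next,G,CA,-0.05
prev,P,H,0.1
prev,P,N,0.8
prev,P,CA,-0.2
next,P,H,-0.05
next,P,N,-0.6
next,P,CA,-1.8
next,P,CB,-0.3
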