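# Averaged X-H neutron bond distances (Angstrom) used to re-normalize
# X-H bonds before pseudoatom parametrization.  Key = element of the heavy
# atom, optionally suffixed with its coordination number (element.n);
# the bare element key is the fallback.
C.4 1.083
C.3 1.083
C.2 1.056
C   1.083
N.4 1.033
N   1.009
O   0.983
S   1.338
B   1.185
Si  1.480
P   1.415
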