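# synthetic worked example: As(III) uptake (ug/g) with and without a
# ten-fold excess of a competing heavy metal
adsorbent,metal,Q_with,Q_without
S,Cu2+,78.7,100
S-conj1,Cu2+,99.2,100
S-conj2,Cu2+,98.7,100
S-conj8,Cu2+,94.5,100
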