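name	description	composition	mass	charge
1CH2OCO	sn-1 glycerol carbon plus ester group	C2H2O2	58.036	-0.05
2CHOCO	sn-2 glycerol carbon plus ester group	C2H1O2	57.028	-0.05
3CH2OCO	sn-3 glycerol carbon plus ester group	C2H2O2	58.036	-0.05
CHCH	CH=CH alkene bead	C2H2	26.037	0
C2H4E	CH2CH2 bead adjacent to a CHOCO/CH2OCO bead	C2H4	28.053	0.05
C2H4	CH2CH2 bead not adjacent to a CHOCO/CH2OCO bead	C2H4	28.053	0
C3H6E	CH2CH2CH2 bead adjacent to a CHOCO/CH2OCO bead	C3H6	42.080	0.05
C3H6	CH2CH2CH2 bead not adjacent to a CHOCO/CH2OCO bead	C3H6	42.080	0
C3H7T	terminal CH2CH2CH3 bead	C3H7	43.088	0
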