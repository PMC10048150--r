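gene	dnaworks_score	our_method	ssc	experimental
ygiD	6.485	EASY	HARD	HARD
yghX	6.756	EASY	HARD	EASY
insD-1	4.512	EASY	HARD	EASY
ydgJ	6.5	HARD	EASY	HARD
waaJ	54.875	HARD	EASY	HARD
wbbH	64.955	HARD	HARD	HARD
fabR	6.084	EASY	EASY	EASY
yhiL	41.894	HARD	EASY	HARD
ycbJ	9.622	EASY	EASY	EASY
ypfJ	6.625	EASY	HARD	HARD
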