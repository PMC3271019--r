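pattern	category
polymerase	RNA/DNA polymerase
\bRdRP\b	RNA/DNA polymerase
\bRVT\b	RNA/DNA polymerase
exonuclease	Exo/Endonuclease
endonuclease	Exo/Endonuclease
\bnuclease\b	Exo/Endonuclease
helicase	Helicase
tRNA[-_ ]?synt	tRNA synthetase
primase	Primase
^PF01353$	GFP contamination
\bGFP\b	GFP contamination
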