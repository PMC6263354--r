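# Synthetic sigma70 promoter cores (-35 to +1; 36 bp each: -35 hexamer,
# 17 bp spacer, -10 hexamer, 6 bp discriminator, +1 base).
# These are SYNTHETIC stand-ins for the four named constitutive promoter
# backbones, built with the canonical sigma70 architecture. The original
# registry/literature sequences contain internal >5 bp direct repeats and
# would not pass the library's own synthesis screens, so repeat-free
# synthetic cores are bundled instead.
name	core
BBa_J23150_syn	TTTACAGCTAGCTCAGTCCTAGGTATAATAGTCGAC
BBa_J23119_syn	TTGACAGCTAGCTCAGTCCTAGGTATAATGGTACCA
apFAB46_syn	TTGACTCATCGGCTCAACTGTTGTACAATCCGATAG
apFAB342_syn	TTGATAGGCTTAACGTAGCATCCTATGATACCTGAT
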