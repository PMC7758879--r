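# Illustrative UPRE-style consensus motifs for examples and tests.
# These are plausible stand-ins for XBP-1s binding elements (ACGT core,
# CCACG box, UPRE A, UPRE B); they are NOT curated matrices from any
# published source.
acgt_core	ACGT
ccacg_box	CCACG
uprea_like	GATGACGTGK
upreb_like	CCACGTCATC
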