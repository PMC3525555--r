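scenario	neg_lnL	k
1-species	67176.8169	2
9-species	67127.7905	10
12-species	65295.6814	13
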