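pathway	reaction
butyrate_synthesis_synthetic	RX0001
butyrate_synthesis_synthetic	RX0002
butyrate_synthesis_synthetic	RX0003
butyrate_synthesis_synthetic	RX0004
butyrate_synthesis_synthetic	RX0005
butyrate_synthesis_synthetic	RX0006
propionate_synthesis_synthetic	RX0101
propionate_synthesis_synthetic	RX0102
propionate_synthesis_synthetic	RX0103
propionate_synthesis_synthetic	RX0104
acetate_synthesis_synthetic	RX0201
acetate_synthesis_synthetic	RX0202
acetate_synthesis_synthetic	RX0203
starch_degradation_synthetic	RX0301
starch_degradation_synthetic	RX0302
starch_degradation_synthetic	RX0303
starch_degradation_synthetic	RX0304
starch_degradation_synthetic	RX0305
mucin_degradation_synthetic	RX0401
mucin_degradation_synthetic	RX0402
mucin_degradation_synthetic	RX0403
mucin_degradation_synthetic	RX0404
mucin_degradation_synthetic	RX0405
mucin_degradation_synthetic	RX0406
mucin_degradation_synthetic	RX0407
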