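sex,age_year,s,pp,m_p,m_np
female,1,0.8223557,0.267,0.047431028099999994,0.13021327189999998
female,2,0.848528137423857,0.89,0.13480995769276724,0.016661904883375725
female,3,0.848528137423857,0.89,0.13480995769276724,0.016661904883375725
female,4,0.9305555555555557,0.89,0.06180555555555543,0.007638888888888873
female,5,0.9104477611940298,0.89,0.07970149253731347,0.009850746268656719
female,6,0.8614213,0.445,0.061667521500000023,0.07691117850000002
female,7,0.8614213,0.2225,0.030833760750000012,0.10774493925000003
female,8,0.8614213,0.11125,0.015416880375000006,0.12316181962500006
female,9,0.8614213,0.055625,0.007708440187500003,0.13087025981250006
female,10,0.8614213,0.0278125,0.0038542200937500015,0.13472447990625006
female,11,0.8614213,0.01390625,0.0019271100468750007,0.13665158995312504
female,12,0.8614213,0.006953125,9.635550234375004e-4,0.13761514497656255
female,13,0.8614213,0.0034765625,4.817775117187502e-4,0.13809692248828132
female,14,0.8614213,0.00173828125,2.408887558593751e-4,0.13833781124414068
female,15,0.8614213,8.69140625e-4,1.2044437792968755e-4,0.13845825562207037
female,16,0.8614213,4.345703125e-4,6.022218896484377e-5,0.1385184778110352
female,17,0.8614213,2.1728515625e-4,3.0111094482421886e-5,0.13854858890551763
female,18,0.8614213,1.08642578125e-4,1.5055547241210943e-5,0.13856364445275884
female,19,0.8614213,5.43212890625e-5,7.527773620605472e-6,0.13857117222637946
female,20,0.8614213,2.716064453125e-5,3.763886810302736e-6,0.13857493611318975
female,21,0.8614213,1.3580322265625e-5,1.881943405151368e-6,0.1385768180565949
female,22,0.8614213,6.7901611328125e-6,9.40971702575684e-7,0.13857775902829747
female,23,0.8614213,3.39508056640625e-6,4.70485851287842e-7,0.13857822951414875
female,24,0.8614213,1.697540283203125e-6,2.35242925643921e-7,0.13857846475707442
female,25,0.8614213,8.487701416015625e-7,1.176214628219605e-7,0.13857858237853724
female,26,0.8614213,4.2438507080078126e-7,5.881073141098025e-8,0.13857864118926866
female,27,0.8614213,2.1219253540039063e-7,2.9405365705490123e-8,0.13857867059463436
female,28,0.8614213,1.0609626770019531e-7,1.4702682852745062e-8,0.1385786852973172
female,29,0.8614213,5.304813385009766e-8,7.351341426372531e-9,0.13857869264865863
female,30,0.8614213,2.652406692504883e-8,3.6756707131862654e-9,0.13857869632432934
female,31,0.8614213,1.3262033462524414e-8,1.8378353565931327e-9,0.1385786981621647
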