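name,epsilon_host,epsilon_inclusion,volume_fraction_inclusion
water,80.1,25.3,0.00
etoh_10,80.1,25.3,0.10
etoh_20,80.1,25.3,0.20
etoh_30,80.1,25.3,0.30
etoh_40,80.1,25.3,0.40
etoh_50,80.1,25.3,0.50
etoh_60,25.3,80.1,0.40
etoh_70,25.3,80.1,0.30
etoh_80,25.3,80.1,0.20
etoh_90,25.3,80.1,0.10
ethanol,25.3,80.1,0.00
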