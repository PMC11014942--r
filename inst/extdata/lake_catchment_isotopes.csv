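sample_id,sample_type,d18O,d17O,D17O,d15N,sigma_d18O,sigma_D17O,sigma_d15N
sediment_mean,sediment,4.6,,1.3,,0.3,0.8,0.6
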