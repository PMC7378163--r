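label,distribution_loss_frac,horizon_year
RCP2.6,0.49,2100
RCP6.0,0.71,2100
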