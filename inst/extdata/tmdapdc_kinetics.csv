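variant,substrate,KM,KM_err,kcat,kcat_err
Wild-type,DAP,0.27,0.06,0.075,0.004
E315T,APA,0.32,0.03,0.2,0.004
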