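{"schema":"1","model_form":"linear","time_label":"1h","A":0.15,"B":12.518,"se_A":0.013,"se_B":0.158,"phi":60,"df":null,"source":"user_supplied"}
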