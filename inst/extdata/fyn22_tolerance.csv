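stress,condition,initial_count,final_count
acid,pH 2.0,3.78,3.25
acid,pH 3.0,3.78,3.52
acid,pH 4.0,3.78,3.64
bile_salt,0.5%,3.62,3.39
bile_salt,1.0%,3.62,3.27
bile_salt,1.5%,3.62,3.16
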