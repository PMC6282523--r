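{"name":"obs_20pct_treated","design":"observational","phi":0.693147180559945,"theta":0.693147180559945,"gamma":0,"alpha0":null,"alpha1":null,"alpha_y":null,"beta_x0":0.405465108108164,"beta_x1":0.405465108108164,"beta_a0":-0.693147180559945,"beta_a1":-0.693147180559945,"n_dev":10000,"n_test":100000,"target_pa0":0.2,"target_pa1":0.2,"target_py":0.2}
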