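{"seed":1,"profiles":{"grade1-2":{"name":"grade1-2","n":43,"means":{"k_true":1.8,"g_old":0.15,"beta_same":0.7,"b_wm":0.5,"d_novel":0.7,"tau_ltm":0.45,"b_ltm":0.15,"g_old_ltm":0.13},"sds":{"k_true":0.5,"g_old":0.08,"beta_same":0.08,"b_wm":0.1,"d_novel":0.08,"tau_ltm":0.12,"b_ltm":0.12,"g_old_ltm":0.1}},"grade5-7":{"name":"grade5-7","n":39,"means":{"k_true":3,"g_old":0.2,"beta_same":0.7,"b_wm":0.65,"d_novel":0.82,"tau_ltm":0.53,"b_ltm":0.15,"g_old_ltm":0.29},"sds":{"k_true":0.5,"g_old":0.08,"beta_same":0.08,"b_wm":0.1,"d_novel":0.08,"tau_ltm":0.12,"b_ltm":0.12,"g_old_ltm":0.1}},"adult":{"name":"adult","n":42,"means":{"k_true":3.6,"g_old":0.2,"beta_same":0.7,"b_wm":0.75,"d_novel":0.9,"tau_ltm":0.53,"b_ltm":0.15,"g_old_ltm":0.32},"sds":{"k_true":0.6,"g_old":0.08,"beta_same":0.08,"b_wm":0.1,"d_novel":0.08,"tau_ltm":0.12,"b_ltm":0.12,"g_old_ltm":0.1}}},"pool_wm_lures":false,"binding_include_all":false,"adjust_rule":"k_floor","prior_width":1}
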