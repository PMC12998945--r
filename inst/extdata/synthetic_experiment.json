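{"mechanism":"simple","variants":{"wt":{"k1":290543.503115752,"k_minus1":62.8326995782745,"k2":11.6193177809148},"mutA":{"k1":494421.355469808,"k_minus1":447.563235058782,"k2":60.0760104284874},"mutB":{"k1":30756.5640483835,"k_minus1":2676.19727285907,"k2":910.580542137826},"double":{"k1":52338.8130291023,"k_minus1":19062.8051497956,"k2":23540.128248882}},"config":{"seed":101,"injected_specific_k2_fold":5}}
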