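{"model_id": "ratkowsky1", "cc": 2.999, "k1": 0.084, "k2": 0.090, "T1": 16.502, "T2": 36.051}
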