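{"D001": "CCO", "D002": "c1ccncc1"}
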