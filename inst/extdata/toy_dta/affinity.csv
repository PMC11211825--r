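"","T001","T002"
"D001",5.2,NA
"D002",6.8,5.0
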