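condition,category,count
present,1,3
present,2,3
present,3,12
present,4,33
absent,1,33
absent,2,9
absent,3,14
absent,4,2
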