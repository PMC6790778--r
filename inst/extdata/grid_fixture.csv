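cell_id,date
6,2018-01-01
6,2018-01-03
6,2018-01-07
11,2018-01-05
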