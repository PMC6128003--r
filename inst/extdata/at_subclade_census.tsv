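subclade	n
I	44
II	15
III	45
IV	4
V	10
VI	14
VII	7
VIII	21
IX	5
X	18
XI	30
XII	10
XIII	10
XVI	1
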