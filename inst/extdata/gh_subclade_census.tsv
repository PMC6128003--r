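subclade	n
I	13
II	28
III	89
IV	12
V	18
VI	30
VII	17
VIII	40
IX	18
X	43
XI	93
XII	128
XIII	13
Others	1
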