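model,population,delta
dp,I,10.1472
dp,II,7.1942
np,I,5.6528
np,II,4.9476
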