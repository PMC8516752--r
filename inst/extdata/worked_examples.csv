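item,target,response
A1,water,water
A2,water,wayer
A3,water,
B1,The big blue house is for sale,The big blue house is for sale
B2,The big blue house is for sale,the hous is for sale
B3,The big blue house is for sale,sail
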