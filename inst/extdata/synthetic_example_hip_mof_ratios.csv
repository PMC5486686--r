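sex,age,ratio
female,45,7.0
female,55,6.2
female,65,4.8
female,75,3.2
female,85,2.3
female,95,2.0
male,45,5.5
male,55,4.8
male,65,3.8
male,75,2.8
male,85,2.1
male,95,1.9
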