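variability,baseline,none,early,variable_mild,variable_severe,late_mild,late_severe,prolonged_mild,prolonged_severe
moderate,b110_160,1,2,2,3,3,3,3,4
moderate,gt160,2,2,3,3,3,4,3,4
moderate,b80_110,3,3,3,4,4,4,4,4
moderate,lt80,4,4,4,4,4,4,4,4
minimal,b110_160,3,3,3,4,3,4,4,4
minimal,gt160,3,3,4,4,4,5,4,4
minimal,b80_110,4,4,4,5,5,5,5,5
minimal,lt80,5,5,5,5,5,5,5,5
undetectable,any,4,5,5,5,5,5,5,5
marked,any,3,3,3,3,3,4,3,4
sinusoidal,any,4,4,4,4,5,5,5,5
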