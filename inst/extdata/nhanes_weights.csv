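period,gender,mean_weight_kg,source
1960-62,men,76.9,paper
1960-62,women,64.9,paper
1971-74,men,NA,absent
1971-74,women,NA,absent
1976-80,men,NA,absent
1976-80,women,NA,absent
1988-94,men,NA,absent
1988-94,women,NA,absent
1999-2002,men,NA,absent
1999-2002,women,NA,absent
2003-06,men,91.8,paper
2003-06,women,NA,absent
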