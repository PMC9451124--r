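study,region,gender,ages,category,rr,ci_low,ci_high
jacobs1999,Europe/US/Japan,M,40-59,light,1.30,1.20,1.40
jacobs1999,Europe/US/Japan,M,40-59,smoker10plus,1.80,1.70,1.90
gellert2012,US/China/Aus/Japan,MF,60+,current,1.83,1.65,2.03
gellert2012,US/China/Aus/Japan,MF,60+,former,1.34,1.28,1.40
carter2015,US,M,55+,current,2.80,2.80,2.90
carter2015,US,F,55+,current,2.80,2.70,2.90
shavelle2008,US/Asia/Europe,MF,adults,light,1.47,1.37,1.80
shavelle2008,US/Asia/Europe,MF,adults,moderate,2.02,1.84,2.36
shavelle2008,US/Asia/Europe,MF,adults,heavy,2.38,2.17,2.84
shavelle2008,US/Asia/Europe,MF,adults,former,1.31,1.07,1.39
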