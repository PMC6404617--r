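variant,timepoint,n_counted,n_inclusions,als_associated,expected_consequence
WT,24,656,5,FALSE,N/A
WT,48,742,6,FALSE,N/A
G93A,24,333,78,TRUE,Steric clash
G93A,48,503,243,TRUE,Steric clash
E40D,24,187,64,FALSE,"Loss of van der Waals, Steric clash"
E40D,48,267,61,FALSE,"Loss of van der Waals, Steric clash"
E40G,24,267,78,TRUE,Loss of van der Waals
E40G,48,238,186,TRUE,Loss of van der Waals
E40Q,24,217,0,FALSE,None
E40Q,48,229,0,FALSE,None
E40V,24,116,28,FALSE,Steric clash
E40V,48,147,37,FALSE,Steric clash
E133D,24,219,0,FALSE,None
E133D,48,197,0,FALSE,None
E133G,24,221,0,FALSE,None
E133G,48,288,0,FALSE,None
E133L,24,275,0,FALSE,None
E133L,48,373,0,FALSE,None
E133M,24,243,0,FALSE,None
E133M,48,265,0,FALSE,None
E133V,24,324,38,TRUE,Steric clash
E133V,48,254,62,TRUE,Steric clash
E133Del,24,192,12,TRUE,Loss of H-bonds
E133Del,48,255,60,TRUE,Loss of H-bonds
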