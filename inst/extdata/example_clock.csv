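#name=example_clock
#transform=identity
#adult_age=20
#output_kind=age_years
cpg,weight
(Intercept),31.569173204479739
cg27239181,3.1694237031042576
cg01287140,2.2275633504614234
cg60693060,3.368529487401247
cg17313490,3.9850175543688238
cg39261342,3.0699871690012515
cg39163732,3.9332281281240284
cg26071172,3.3428551205433905
cg05059425,2.5891554243862629
cg00414418,2.7167259692214429
cg13011878,2.3506295061670244
cg39678368,3.0976347723044455
cg14996200,3.010903405956924
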