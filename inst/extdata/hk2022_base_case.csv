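outcome,strategy,cost_hkd,cost_usd,incr_cost_hkd,incr_cost_usd,effectiveness,incr_effectiveness,icer_hkd,icer_usd,dominant,incr_cost_hkd_alt,note
ser,SVLs,34320,4372,NA,NA,-4.86,NA,NA,NA,FALSE,NA,reference
ser,BSLs,46621,5939,12301,1567,-0.40,4.46,2763,352,FALSE,NA,
ser,DIMS,63036,8030,28715,3658,1.68,6.54,4388,559,FALSE,NA,
ser,"Atropine eye drops, 0.01%",49070,6251,14750,1879,1.98,6.84,2159,275,FALSE,NA,
ser,"Daily disposable CLs",93588,11922,56268,7550,1.50,6.36,9318,1187,FALSE,59268,published incremental cost 56268 conflicts with published totals (93588-34320=59268); suspected typo
ser,RGPCLs,75517,9620,41197,5248,1.80,6.66,6186,788,FALSE,NA,
ser,HALs,58592,7464,24272,3092,2.04,6.90,3517,448,FALSE,NA,
ser,MSCLs,88313,11250,54000,6879,1.56,6.42,8407,1071,FALSE,NA,
ser,PALs,66858,8517,32538,4145,0.78,5.64,5770,735,FALSE,NA,
ser,Outdoor,34108,4345,-204,-26,0.96,5.82,-39,-5,TRUE,NA,published ICER -39 is not the quotient of the published increments (-204/5.82 = -35); unrounded-intermediate artifact
ser,"Atropine eye drops, 0.05%",43615,6193,14303,1822,3.42,8.28,1727,220,TRUE,NA,published total 43615 conflicts with its own incremental (34320+14303=48623) and US$ column (6193x7.85=48615); suspected total-cost typo
ser,"Red light therapy",90102,11478,55782,7106,3.54,8.40,6641,846,TRUE,NA,
al,SVLs,34320,4372,NA,NA,-2.46,NA,NA,NA,FALSE,NA,reference
al,BSLs,46621,5939,12301,1567,0.40,2.86,4302,548,FALSE,NA,published effectiveness 0.40 differs from 6x the annual input (0.42)
al,DIMS,63036,8030,28715,3658,0.96,3.42,8400,1070,FALSE,NA,
al,"Atropine eye drops, 0.01%",49070,6251,14750,1879,1.02,3.48,4239,540,FALSE,NA,
al,"Daily disposable CLs",93588,11922,59268,7550,0.72,3.18,18636,2374,FALSE,NA,
al,RGPCLs,75517,9620,41197,5248,0.32,2.78,14821,1888,FALSE,NA,published effectiveness 0.32 differs from 6x the annual input (0.30)
al,HALs,58592,7464,24272,3092,1.02,3.48,6979,889,FALSE,NA,
al,MSCLs,88313,11250,54000,6879,0.39,2.85,18950,2414,FALSE,NA,published effectiveness 0.39 differs from 6x the annual input (0.42)
al,PALs,66858,8517,32538,4145,0.90,3.36,9687,1234,FALSE,NA,published effectiveness is +0.90 although the annual input (+0.15 mm/yr elongation) implies -0.90 on the benefit scale
al,"Red light therapy",90102,11478,55782,7106,1.50,3.96,14083,1794,FALSE,NA,
al,Orthokeratology,120474,15347,86154,10975,2.16,4.62,18652,2376,TRUE,NA,
al,Outdoor,34108,4345,-204,-26,0.60,3.06,-63,-8,TRUE,NA,
al,"Atropine eye drops, 0.05%",43615,6193,14303,1822,1.80,4.26,3360,428,TRUE,NA,published total 43615 conflicts with its own incremental (34320+14303=48623) and US$ column (6193x7.85=48615); suspected total-cost typo
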