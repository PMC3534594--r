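subject,ga_weeks,weight_kg,mpa,dao,da,aao,svc,uv,rpa,lpa
1,39,4.0,278,197,188,155,107,107,53,44
2,35,2.2,440,389,287,247,279,168,NA,NA
3,36,3.0,351,268,196,145,136,140,NA,NA
4,37,3.0,274,213,186,182,170,127,45,39
5,38,2.9,278,279,245,157,125,101,13,6
6,34,2.0,341,256,173,208,107,125,74,51
7,37,3.7,265,383,243,212,128,253,4,19
8,37,3.3,315,173,174,188,145,160,92,54
9,35,2.5,384,274,262,215,156,137,NA,NA
10,30,2.2,440,418,262,272,112,311,NA,NA
11,37,3.4,326,261,206,217,144,134,30,30
12,38,2.7,229,163,223,177,156,156,7,7
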