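# SYNTHETIC ANNOTATION OVERLAY for the CML first-line trial registry.
# The published table prints trial identities, years, and arm compositions
# only. Per-arm enrollments (n_a, n_b) and per-comparison outcome
# annotations (outcome_class, verdict, basis) in this file are SYNTHETIC:
# they were not printed in the source and are hand-tuned so the valued
# timeline mirrors the narrative eras (busulfan overturned 1994,
# hydroxyurea 1995, imatinib era from 2003, imatinib overturned 2010).
# Structural columns (trial_id, year, regimen pairs) match
# cml_table_structure.csv; multi-arm trials are expanded to all unordered
# arm pairs.
# outcome_class: weak|strong|os  verdict: a|b|tie  basis: sig|noninf|ns
trial_id,year,regimen_a,n_a,regimen_b,n_b,outcome_class,verdict,basis
R10,1968,Busulfan,102,Radiation,98,os,a,sig
R08,1972,Busulfan,70,DBM,68,weak,tie,ns
R09,1983,Busulfan,85,DBM,88,os,tie,ns
R15,1993,Busulfan,186,Hydrea,194,os,tie,ns
R14,1994,Busulfan,183,Hydrea,194,os,b,sig
R14,1994,Busulfan,183,IFNA,133,os,b,sig
R14,1994,Hydrea,194,IFNA,133,os,tie,ns
R13,1995,Busulfan,80,Hydrea,81,os,tie,ns
R13,1995,Busulfan,80,IFNA,79,os,b,sig
R13,1995,Hydrea,81,IFNA,79,os,b,sig
R12,1995,Busulfan,105,Hydrea,110,os,b,sig
R12,1995,Busulfan,105,Busulfan/IFNA,108,strong,b,sig
R12,1995,Busulfan,105,Hydrea/IFNA,112,strong,b,sig
R12,1995,Hydrea,110,Busulfan/IFNA,108,strong,b,sig
R12,1995,Hydrea,110,Hydrea/IFNA,112,strong,b,sig
R12,1995,Busulfan/IFNA,108,Hydrea/IFNA,112,os,tie,ns
R11,1996,Busulfan,159,IFNA,162,os,b,sig
R16,1997,IFNA,360,IFNA/LoDAC,361,os,b,sig
R17,2002,IFNA,210,IFNA/LoDAC,208,os,tie,ns
R18,2002,Hydrea/IFNA,170,IFNA/LoDAC,166,strong,tie,ns
R19,2003,IFNA/LoDAC,553,Imatinib,553,strong,b,sig
R20,2003,IFNA,175,MRD allo-SCT,166,os,tie,ns
R21,2004,Busulfan,90,Hydrea,93,os,tie,ns
R22,2005,IFNA/HiDAC,410,IFNA/LoDAC,411,strong,tie,ns
R23,2008,Imatinib,157,Imatinib-HD,162,weak,tie,ns
R24,2009,Imatinib,159,Imatinib-HD,157,weak,tie,ns
R26,2010,Dasatinib,259,Imatinib,260,strong,a,sig
R27,2010,Imatinib,223,Imatinib-HD,171,strong,tie,ns
R27,2010,Imatinib,223,Imatinib/IFNA,221,strong,b,sig
R27,2010,Imatinib,223,Imatinib/LoDAC,172,strong,tie,ns
R27,2010,Imatinib-HD,171,Imatinib/IFNA,221,strong,b,sig
R27,2010,Imatinib-HD,171,Imatinib/LoDAC,172,strong,tie,ns
R27,2010,Imatinib/IFNA,221,Imatinib/LoDAC,172,strong,a,sig
R35,2010,Imatinib,283,Nilotinib,282,strong,b,sig
R28,2011,Imatinib,400,Imatinib-HD,420,weak,b,sig
R28,2011,Imatinib,400,Imatinib/IFNA,430,weak,tie,ns
R28,2011,Imatinib-HD,420,Imatinib/IFNA,430,weak,tie,ns
R29,2011,IFNA/Imatinib,98,Imatinib,97,strong,tie,ns
R31,2012,Bosutinib,250,Imatinib,252,weak,tie,ns
R30,2012,Dasatinib,130,Imatinib,130,strong,a,sig
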