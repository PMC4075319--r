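# Structural transcription of the published registry of randomized trials of
# first-line treatment for chronic-phase chronic myelogenous leukemia:
# trial identity (keyed by the source's citation tag), publication year, and
# arm composition (one row per trial arm, regimen labels as printed).
# Publication years were reconstructed from the source narrative and the
# table's chronological ordering; see the package documentation.
# Note: the source lists the nilotinib trial (R35) out of citation order;
# this file follows the table as printed.
trial_id,year,arm
R10,1968,Busulfan
R10,1968,Radiation
R08,1972,Busulfan
R08,1972,DBM
R09,1983,Busulfan
R09,1983,DBM
R15,1993,Busulfan
R15,1993,Hydrea
R14,1994,Busulfan
R14,1994,Hydrea
R14,1994,IFNA
R13,1995,Busulfan
R13,1995,Hydrea
R13,1995,IFNA
R12,1995,Busulfan
R12,1995,Hydrea
R12,1995,Busulfan/IFNA
R12,1995,Hydrea/IFNA
R11,1996,Busulfan
R11,1996,IFNA
R16,1997,IFNA
R16,1997,IFNA/LoDAC
R17,2002,IFNA
R17,2002,IFNA/LoDAC
R18,2002,Hydrea/IFNA
R18,2002,IFNA/LoDAC
R19,2003,IFNA/LoDAC
R19,2003,Imatinib
R20,2003,IFNA
R20,2003,MRD allo-SCT
R21,2004,Busulfan
R21,2004,Hydrea
R22,2005,IFNA/HiDAC
R22,2005,IFNA/LoDAC
R23,2008,Imatinib
R23,2008,Imatinib-HD
R24,2009,Imatinib
R24,2009,Imatinib-HD
R26,2010,Dasatinib
R26,2010,Imatinib
R27,2010,Imatinib
R27,2010,Imatinib-HD
R27,2010,Imatinib/IFNA
R27,2010,Imatinib/LoDAC
R35,2010,Imatinib
R35,2010,Nilotinib
R28,2011,Imatinib
R28,2011,Imatinib-HD
R28,2011,Imatinib/IFNA
R29,2011,IFNA/Imatinib
R29,2011,Imatinib
R31,2012,Bosutinib
R31,2012,Imatinib
R30,2012,Dasatinib
R30,2012,Imatinib
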