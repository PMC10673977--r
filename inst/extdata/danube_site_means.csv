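site,period,metal,mean_ugL
S1,APR_SEP,As,1.21
S1,APR_SEP,Cr,1.45
S1,APR_SEP,Cu,4.29
S1,APR_SEP,Fe,626.8
S1,APR_SEP,Mn,55.26
S1,APR_SEP,Ni,2.55
S1,APR_SEP,Pb,1.22
S1,APR_SEP,Zn,16.45
S1,OCT_MAR,As,1.3
S1,OCT_MAR,Cr,1.07
S1,OCT_MAR,Cu,3.33
S1,OCT_MAR,Fe,405.5
S1,OCT_MAR,Mn,38.88
S1,OCT_MAR,Ni,2.41
S1,OCT_MAR,Pb,0.93
S1,OCT_MAR,Zn,14.35
S2,APR_SEP,As,1.27
S2,APR_SEP,Cr,1.3
S2,APR_SEP,Cu,4.17
S2,APR_SEP,Fe,518.3
S2,APR_SEP,Mn,48.26
S2,APR_SEP,Ni,2.64
S2,APR_SEP,Pb,1.61
S2,APR_SEP,Zn,14.78
S2,OCT_MAR,As,1.27
S2,OCT_MAR,Cr,0.93
S2,OCT_MAR,Cu,3.37
S2,OCT_MAR,Fe,336.1
S2,OCT_MAR,Mn,44.78
S2,OCT_MAR,Ni,2.29
S2,OCT_MAR,Pb,1.37
S2,OCT_MAR,Zn,14.44
S3,APR_SEP,As,1.34
S3,APR_SEP,Cr,1.42
S3,APR_SEP,Cu,4.4
S3,APR_SEP,Fe,634.73
S3,APR_SEP,Mn,55.26
S3,APR_SEP,Ni,2.64
S3,APR_SEP,Pb,1.42
S3,APR_SEP,Zn,17.66
S3,OCT_MAR,As,1.45
S3,OCT_MAR,Cr,1.01
S3,OCT_MAR,Cu,3.71
S3,OCT_MAR,Fe,452.9
S3,OCT_MAR,Mn,34.37
S3,OCT_MAR,Ni,2.71
S3,OCT_MAR,Pb,1.03
S3,OCT_MAR,Zn,16.25
S4,APR_SEP,As,1.35
S4,APR_SEP,Cr,1.8
S4,APR_SEP,Cu,3.48
S4,APR_SEP,Fe,170.67
S4,APR_SEP,Mn,40
S4,APR_SEP,Ni,3.1
S4,APR_SEP,Pb,1.14
S4,APR_SEP,Zn,12.93
S4,OCT_MAR,As,1.28
S4,OCT_MAR,Cr,1.58
S4,OCT_MAR,Cu,3.81
S4,OCT_MAR,Fe,208.3
S4,OCT_MAR,Mn,26
S4,OCT_MAR,Ni,2.45
S4,OCT_MAR,Pb,1.3
S4,OCT_MAR,Zn,12.79
S5,APR_SEP,As,1.37
S5,APR_SEP,Cr,1.11
S5,APR_SEP,Cu,3.74
S5,APR_SEP,Fe,436.76
S5,APR_SEP,Mn,43.42
S5,APR_SEP,Ni,2.87
S5,APR_SEP,Pb,1.2
S5,APR_SEP,Zn,11.98
S5,OCT_MAR,As,1.46
S5,OCT_MAR,Cr,1.42
S5,OCT_MAR,Cu,3.62
S5,OCT_MAR,Fe,381.2
S5,OCT_MAR,Mn,31.91
S5,OCT_MAR,Ni,2.3
S5,OCT_MAR,Pb,1.12
S5,OCT_MAR,Zn,16.13
S6,APR_SEP,As,1.2
S6,APR_SEP,Cr,1.49
S6,APR_SEP,Cu,4.11
S6,APR_SEP,Fe,590.5
S6,APR_SEP,Mn,72.1
S6,APR_SEP,Ni,2.86
S6,APR_SEP,Pb,1.45
S6,APR_SEP,Zn,14.38
S6,OCT_MAR,As,1.7
S6,OCT_MAR,Cr,1.83
S6,OCT_MAR,Cu,3.79
S6,OCT_MAR,Fe,511
S6,OCT_MAR,Mn,65.71
S6,OCT_MAR,Ni,2.6
S6,OCT_MAR,Pb,1.55
S6,OCT_MAR,Zn,15.8
S7,APR_SEP,As,1.31
S7,APR_SEP,Cr,1.44
S7,APR_SEP,Cu,4.03
S7,APR_SEP,Fe,666.67
S7,APR_SEP,Mn,56.84
S7,APR_SEP,Ni,2.27
S7,APR_SEP,Pb,1.14
S7,APR_SEP,Zn,16.8
S7,OCT_MAR,As,1.6
S7,OCT_MAR,Cr,1.65
S7,OCT_MAR,Cu,4.17
S7,OCT_MAR,Fe,528.5
S7,OCT_MAR,Mn,36.3
S7,OCT_MAR,Ni,2.8
S7,OCT_MAR,Pb,1.34
S7,OCT_MAR,Zn,19.39
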