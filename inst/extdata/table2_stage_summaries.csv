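stage_label,n,group,mean,sd,cv
<7 days,17,ndl_indicator,16.63,1.37,8.24
7 days,26,ndl_indicator,19.83,1.26,6.35
14 days,59,ndl_indicator,20.31,1.36,6.70
21 days,98,ndl_indicator,17.94,1.10,6.13
28 days,39,ndl_indicator,14.49,0.74,5.11
2 months,75,ndl_indicator,15.90,1.25,7.86
3 months,75,ndl_indicator,15.24,1.14,7.48
4 months,92,ndl_indicator,15.22,1.14,7.49
5 months,88,ndl_indicator,12.83,0.97,7.56
6 months,88,ndl_indicator,10.82,0.89,8.23
7 months,69,ndl_indicator,15.39,1.46,9.49
8 months,39,ndl_indicator,15.71,1.32,8.40
9 months,29,ndl_indicator,13.81,1.28,9.27
10 months,29,ndl_indicator,11.63,0.88,7.57
11 months,29,ndl_indicator,10.48,0.72,6.87
12 months,29,ndl_indicator,7.75,0.54,7.00
>1 year of feeding,39,ndl_indicator,0.343,0.035,10.20
<7 days,17,non_ortho,1.71,0.23,13.31
7 days,26,non_ortho,3.81,0.50,13.15
14 days,59,non_ortho,3.04,0.44,14.52
21 days,98,non_ortho,2.45,0.32,13.00
28 days,39,non_ortho,2.37,0.22,9.12
2 months,75,non_ortho,2.06,0.20,9.81
3 months,75,non_ortho,1.65,0.15,9.02
4 months,92,non_ortho,1.47,0.18,12.22
5 months,88,non_ortho,1.39,0.19,13.54
6 months,88,non_ortho,1.36,0.09,6.72
7 months,69,non_ortho,1.25,0.07,5.77
8 months,39,non_ortho,1.16,0.10,8.89
9 months,29,non_ortho,1.15,0.12,10.49
10 months,29,non_ortho,0.74,0.12,16.02
11 months,29,non_ortho,0.42,0.06,14.89
12 months,29,non_ortho,0.15,0.03,18.82
>1 year of feeding,39,non_ortho,0.14,0.05,32.16
<7 days,17,mono_ortho,7.84,0.75,9.52
7 days,26,mono_ortho,14.85,1.19,8.01
14 days,59,mono_ortho,12.19,1.04,8.53
21 days,98,mono_ortho,9.85,0.83,8.43
28 days,39,mono_ortho,8.56,0.94,10.98
2 months,75,mono_ortho,8.99,0.74,8.26
3 months,75,mono_ortho,7.02,0.61,8.65
4 months,92,mono_ortho,6.21,0.65,10.44
5 months,88,mono_ortho,5.23,0.55,10.43
6 months,88,mono_ortho,3.37,0.42,12.42
7 months,69,mono_ortho,4.23,0.38,8.95
8 months,39,mono_ortho,3.55,0.43,12.04
9 months,29,mono_ortho,2.85,0.37,12.84
10 months,29,mono_ortho,2.35,0.27,11.54
11 months,29,mono_ortho,1.76,0.22,12.75
12 months,29,mono_ortho,1.02,0.17,17.12
>1 year of feeding,39,mono_ortho,0.21,0.04,17.45
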