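rank,window,si,lp,hp,p_lp,p_hp,sig_lp,sig_hp
1,n200,-7.68,-9.13,-7.93,0.002,0.541,TRUE,FALSE
2,n200,-7.85,-9.13,-7.89,0.033,0.936,FALSE,FALSE
3,n200,-8.92,-9.13,-7.68,0.545,0.010,FALSE,TRUE
4,n200,-7.74,-9.13,-7.91,0.003,0.694,TRUE,FALSE
5,n200,-7.03,-9.13,-8.06,0.000,0.023,TRUE,FALSE
6,n200,-8.09,-9.13,-7.85,0.014,0.584,TRUE,FALSE
7,n200,-8.18,-9.32,-7.89,0.031,0.455,FALSE,FALSE
8,n200,-8.94,-9.17,-7.89,0.649,0.036,FALSE,FALSE
9,n200,-8.19,-9.32,-7.89,0.012,0.560,TRUE,FALSE
10,n200,-8.54,-9.25,-7.89,0.221,0.177,FALSE,FALSE
11,n200,-10.50,-8.85,-7.89,0.009,0.000,TRUE,TRUE
12,n200,-10.42,-8.87,-7.89,0.000,0.000,TRUE,TRUE
1,400-800,5.37,2.51,4.35,0.000,0.020,TRUE,TRUE
2,400-800,2.87,2.51,4.85,0.442,0.000,FALSE,TRUE
3,400-800,3.64,2.51,4.70,0.031,0.057,FALSE,FALSE
4,400-800,5.42,2.51,4.34,0.000,0.019,TRUE,TRUE
5,400-800,4.69,2.51,4.49,0.000,0.666,TRUE,FALSE
6,400-800,5.15,2.51,4.40,0.000,0.070,TRUE,FALSE
7,400-800,2.39,2.54,4.52,0.749,0.000,FALSE,TRUE
8,400-800,3.44,2.33,4.52,0.052,0.057,FALSE,FALSE
9,400-800,1.97,2.62,4.52,0.135,0.000,FALSE,TRUE
10,400-800,0.96,2.82,4.52,0.001,0.000,TRUE,TRUE
11,400-800,2.75,2.46,4.52,0.564,0.000,FALSE,TRUE
12,400-800,3.57,2.30,4.52,0.007,0.034,TRUE,FALSE
1,800-1200,2.29,0.44,2.17,0.000,0.727,TRUE,FALSE
2,800-1200,0.87,0.44,2.45,0.341,0.000,FALSE,TRUE
3,800-1200,1.25,0.44,2.37,0.131,0.044,FALSE,FALSE
4,800-1200,2.87,0.44,2.05,0.000,0.070,TRUE,FALSE
5,800-1200,2.65,0.44,2.09,0.000,0.220,TRUE,FALSE
6,800-1200,3.19,0.44,1.99,0.000,0.016,TRUE,TRUE
7,800-1200,1.05,0.32,2.19,0.142,0.025,FALSE,FALSE
8,800-1200,0.91,0.35,2.19,0.302,0.021,FALSE,TRUE
9,800-1200,0.41,0.45,2.19,0.920,0.000,FALSE,TRUE
10,800-1200,-1.56,0.85,2.19,0.000,0.000,TRUE,TRUE
11,800-1200,1.16,0.30,2.19,0.030,0.027,FALSE,FALSE
12,800-1200,0.72,0.39,2.19,0.490,0.005,FALSE,TRUE
1,1200-1600,2.23,-0.26,1.62,0.000,0.200,TRUE,FALSE
2,1200-1600,0.37,-0.26,1.99,0.309,0.002,FALSE,TRUE
3,1200-1600,1.50,-0.26,1.77,0.003,0.594,TRUE,FALSE
4,1200-1600,2.23,-0.26,1.62,0.000,0.271,TRUE,FALSE
5,1200-1600,1.61,-0.26,1.74,0.001,0.783,TRUE,FALSE
6,1200-1600,2.40,-0.26,1.59,0.000,0.163,TRUE,FALSE
7,1200-1600,0.67,-0.44,1.72,0.045,0.057,FALSE,FALSE
8,1200-1600,0.37,-0.38,1.72,0.210,0.012,FALSE,TRUE
9,1200-1600,-0.54,-0.20,1.72,0.526,0.001,FALSE,TRUE
10,1200-1600,-2.11,0.11,1.72,0.000,0.000,TRUE,TRUE
11,1200-1600,0.07,-0.32,1.72,0.347,0.002,FALSE,TRUE
12,1200-1600,0.01,-0.31,1.72,0.529,0.007,FALSE,TRUE
1,1600-2000,1.84,-0.41,1.67,0.000,0.722,TRUE,FALSE
2,1600-2000,0.77,-0.41,1.89,0.032,0.030,FALSE,FALSE
3,1600-2000,1.47,-0.41,1.75,0.001,0.609,TRUE,FALSE
4,1600-2000,2.22,-0.41,1.60,0.000,0.316,TRUE,FALSE
5,1600-2000,1.59,-0.41,1.72,0.000,0.785,TRUE,FALSE
6,1600-2000,2.32,-0.41,1.58,0.000,0.137,TRUE,FALSE
7,1600-2000,0.43,-0.58,1.70,0.073,0.019,FALSE,TRUE
8,1600-2000,0.38,-0.57,1.70,0.151,0.040,FALSE,FALSE
9,1600-2000,-0.73,-0.35,1.70,0.515,0.000,FALSE,TRUE
10,1600-2000,-2.13,-0.07,1.70,0.000,0.000,TRUE,TRUE
11,1600-2000,-0.51,-0.39,1.70,0.832,0.000,FALSE,TRUE
12,1600-2000,0.07,-0.51,1.70,0.293,0.007,FALSE,TRUE
1,2000-3000,1.18,-0.84,1.29,0.000,0.842,TRUE,FALSE
2,2000-3000,-0.02,-0.84,1.53,0.213,0.012,FALSE,TRUE
3,2000-3000,1.70,-0.84,1.19,0.001,0.445,TRUE,FALSE
4,2000-3000,1.75,-0.84,1.18,0.001,0.404,TRUE,FALSE
5,2000-3000,1.11,-0.84,1.30,0.001,0.742,TRUE,FALSE
6,2000-3000,1.91,-0.84,1.14,0.000,0.211,TRUE,FALSE
7,2000-3000,0.83,-1.17,1.27,0.001,0.398,TRUE,FALSE
8,2000-3000,-0.29,-0.94,1.27,0.317,0.036,FALSE,FALSE
9,2000-3000,-1.40,-0.72,1.27,0.276,0.000,FALSE,TRUE
10,2000-3000,-2.68,-0.47,1.27,0.001,0.000,TRUE,TRUE
11,2000-3000,-1.24,-0.75,1.27,0.369,0.000,FALSE,TRUE
12,2000-3000,-0.23,-0.96,1.27,0.182,0.016,FALSE,TRUE
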