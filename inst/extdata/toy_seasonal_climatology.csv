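month,tmin,tmax,hmin,hmean,hmax
1,-5.2,2.1,0.0018,0.0026,0.0035
2,-4.0,3.8,0.0019,0.0028,0.0038
3,-0.5,8.9,0.0024,0.0035,0.0048
4,4.1,15.0,0.0033,0.0048,0.0066
5,9.0,20.8,0.0048,0.0066,0.0090
6,13.2,25.6,0.0068,0.0090,0.0118
7,15.5,28.3,0.0082,0.0105,0.0135
8,14.9,27.4,0.0079,0.0102,0.0130
9,10.8,22.5,0.0060,0.0080,0.0104
10,5.6,15.7,0.0041,0.0056,0.0076
11,0.3,8.0,0.0027,0.0038,0.0052
12,-3.8,3.1,0.0020,0.0029,0.0039
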