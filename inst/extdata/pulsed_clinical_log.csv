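t_s,power_W,tip_z_mm
0,0,-5
1,8,-5
3,8,-5
4,0,-5
21,0,-5
22,8,-5
24,8,-5
25,0,-5
41,0,-5
42,8,-5
44,8,-5
45,0,-5
62,0,-5
63,8,-5
67,8,-5
68,0,-5
84,0,-5
85,8,-5
88,8,-5
89,0,-5
106,0,-5
107,8,-5
111,8,-5
112,0,-5
127,0,-5
128,0,0
129,8,0
131,8,0
132,0,0
147,0,0
148,8,0
151,8,0
152,0,0
168,0,0
169,8,0
172,8,0
173,0,0
189,0,0
190,8,0
194,8,0
195,0,0
210,0,0
211,8,0
215,8,0
216,0,0
231,0,0
232,8,0
234,8,0
235,0,0
250,0,0
251,0,5
252,8,5
254,8,5
255,0,5
271,0,5
272,8,5
274,8,5
275,0,5
290,0,5
291,8,5
294,8,5
295,0,5
311,0,5
312,8,5
315,8,5
316,0,5
331,0,5
332,8,5
336,8,5
337,0,5
352,0,5
353,8,5
357,8,5
358,0,5
374,0,5
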